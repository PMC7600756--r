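## Brute-force oracles and fixture builders shared across test files.
## Oracles are written independently of the implementation paths they check:
## plain loops and set operations, no shared helpers.

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## quick orf_set from a character vector
orfs <- function(seqs, label = "g") {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  orf_set(seqs, label)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## substitute exactly the given positions (to a different base)
mutate_at <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

## random hit table over n_q queries and n_s subjects
random_hits <- function(n_hits, n_q = 10, n_s = 10,
                        qg = "X", sg = "Y") {
  data.frame(query_genome = qg, subject_genome = sg,
             query_id = sprintf("q%02d", sample.int(n_q, n_hits, TRUE)),
             subject_id = sprintf("t%02d", sample.int(n_s, n_hits, TRUE)),
             evalue = signif(10^runif(n_hits, -60, -1), 3),
             pident = round(runif(n_hits, 70, 100), 2),
             pgaps = round(runif(n_hits, 0, 5), 2),
             aln_len = sample(100:1000, n_hits, TRUE),
             score = round(runif(n_hits, 50, 500)),
             stringsAsFactors = FALSE)
}

## exhaustive per-query minimisation with the documented tie chain
oracle_best_hits <- function(hits) {
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    rows <- hits[hits$query_id == q, , drop = FALSE]
    best <- rows[1, , drop = FALSE]
    if (nrow(rows) > 1) {
      for (i in 2:nrow(rows)) {
        r <- rows[i, , drop = FALSE]
        better <-
          r$evalue < best$evalue ||
          (r$evalue == best$evalue && r$pident > best$pident) ||
          (r$evalue == best$evalue && r$pident == best$pident &&
             r$aln_len > best$aln_len) ||
          (r$evalue == best$evalue && r$pident == best$pident &&
             r$aln_len == best$aln_len && r$subject_id < best$subject_id)
        if (better) best <- r
      }
    }
    out[[q]] <- best
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## O(n^2) reciprocity oracle over two best-hit maps
oracle_bbh <- function(fwd, rev) {
  pairs <- list()
  for (i in seq_len(nrow(fwd))) {
    x <- fwd$query_id[i]
    y <- fwd$subject_id[i]
    for (j in seq_len(nrow(rev))) {
      if (rev$query_id[j] == y && rev$subject_id[j] == x) {
        pairs[[length(pairs) + 1L]] <- c(x, y)
      }
    }
  }
  if (!length(pairs)) return(matrix(character(0), ncol = 2))
  m <- do.call(rbind, pairs)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

## repeated-pass transitive closure: merge sets until a fixed point
oracle_components <- function(pairs) {
  sets <- lapply(seq_len(nrow(pairs)),
                 function(i) unique(c(pairs$id_a[i], pairs$id_b[i])))
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(sets)) {
      j <- i + 1L
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, character(1), 1L))]
}

## minimal BBH-pair data.frame builder (as produced by the homology stage)
pairs_df <- function(id_a, id_b, pident = 95, ga = "hybrid", gb = "parent",
                     evalue = 1e-50) {
  n <- length(id_a)
  data.frame(id_a = id_a, id_b = id_b,
             genome_a = rep_len(ga, n), genome_b = rep_len(gb, n),
             pident = rep_len(pident, n), pgaps = rep_len(0, n),
             evalue = rep_len(evalue, n), stringsAsFactors = FALSE)
}

## small GFF3 fixture: n genes each with one mRNA child
write_gff3_fixture <- function(path, n_genes = 3) {
  lines <- c("##gff-version 3")
  for (i in seq_len(n_genes)) {
    g <- sprintf("GENE%03d", i)
    lines <- c(lines,
               sprintf("chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=%s;note=x",
                       i * 1000, i * 1000 + 500, g),
               sprintf("chr1\tsrc\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
                       i * 1000, i * 1000 + 500, g, g))
  }
  writeLines(lines, path)
  path
}
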