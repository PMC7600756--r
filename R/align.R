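#' Alignment parameters
#'
#' Bundles the tunables of the all-vs-all nucleotide alignment stage. The
#' defaults mirror stringent blastn usage: hits are only saved below an
#' expectation value of 0.05, and the built-in aligner scores with
#' match +2 / mismatch -3, gap open 5, gap extend 2 (a gap of length L costs
#' `gap_open + L * gap_extend`). E-values for the built-in backend follow the
#' Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)` with ungapped
#' nucleotide constants.
#'
#' @param evalue_keep maximum e-value for saving a hit (> 0).
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open,gap_extend affine gap costs (non-negative).
#' @param k seed word size of the built-in aligner.
#' @param min_seeds minimum number of shared k-mer seeds on a single
#'   diagonal before a candidate pair is aligned (multi-hit seeding).
#' @param band_pad diagonals added on each side of the seed diagonal range.
#' @param band_max maximum band width (diagonals) for the banded extension.
#' @param both_strands also search the reverse-complement strand.
#' @param lambda,K Karlin-Altschul parameters for the built-in backend.
#' @return A list of class `align_params`.
#' @export
align_params <- function(evalue_keep = 0.05, match = 2L, mismatch = -3L,
                         gap_open = 5L, gap_extend = 2L, k = 11L,
                         min_seeds = 4L, band_pad = 16L, band_max = 256L,
                         both_strands = TRUE, lambda = 0.625, K = 0.41) {
  if (evalue_keep <= 0) stopf("'evalue_keep' must be > 0")
  if (match <= 0) stopf("'match' must be > 0")
  if (mismatch >= 0) stopf("'mismatch' must be < 0")
  if (gap_open < 0 || gap_extend < 0) stopf("gap costs must be >= 0")
  if (k < 4) stopf("'k' must be >= 4")
  if (lambda <= 0 || K <= 0) stopf("'lambda' and 'K' must be > 0")
  structure(list(evalue_keep = evalue_keep, match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), k = as.integer(k),
                 min_seeds = as.integer(min_seeds),
                 band_pad = as.integer(band_pad),
                 band_max = as.integer(band_max),
                 both_strands = isTRUE(both_strands),
                 lambda = lambda, K = K),
            class = "align_params")
}

## canonical empty hit table
empty_hit_table <- function(query_genome, subject_genome) {
  data.frame(query_genome = character(0), subject_genome = character(0),
             query_id = character(0), subject_id = character(0),
             evalue = numeric(0), pident = numeric(0), pgaps = numeric(0),
             aln_len = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Plan the alignment jobs of a pipeline run
#'
#' For a hybrid and P parents (2-4) the pipeline needs 3P+1 alignment jobs:
#' the hybrid against each parent and back (2P cross jobs, for orthologs) and
#' every genome against itself (P+1 self jobs, for paralogs). With two
#' parents this is the canonical set of seven alignment runs.
#'
#' @param hybrid_label genome label of the hybrid.
#' @param parent_labels character vector of 2-4 distinct parent labels.
#' @return A data.frame with columns `query_genome`, `subject_genome`,
#'   `purpose` (one of `ortholog-forward`, `ortholog-reverse`,
#'   `self-paralog`), in deterministic order.
#' @export
plan_jobs <- function(hybrid_label, parent_labels) {
  np <- length(parent_labels)
  if (np < 2L || np > 4L) {
    stopf("between 2 and 4 parental genomes are supported, got %d", np)
  }
  labs <- c(hybrid_label, parent_labels)
  if (anyDuplicated(labs)) stopf("genome labels must be distinct")
  cross <- do.call(rbind, lapply(parent_labels, function(p) {
    data.frame(query_genome = c(hybrid_label, p),
               subject_genome = c(p, hybrid_label),
               purpose = c("ortholog-forward", "ortholog-reverse"),
               stringsAsFactors = FALSE)
  }))
  selfs <- data.frame(query_genome = labs, subject_genome = labs,
                      purpose = "self-paralog", stringsAsFactors = FALSE)
  rbind(cross, selfs)
}

#' E-value from a raw alignment score
#'
#' Karlin-Altschul expectation `E = K * m * n * exp(-lambda * S)` for a raw
#' local alignment score S, query length m and search-space subject length n.
#' Monotonically decreasing in S.
#'
#' @param raw_score raw alignment score(s).
#' @param m query length (>= 1).
#' @param n effective subject/search-space length (>= 1).
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @return Numeric e-value(s).
#' @export
evalue_from_score <- function(raw_score, m, n, lambda = 0.625, K = 0.41) {
  if (any(m < 1) || any(n < 1)) stopf("'m' and 'n' must be >= 1")
  if (lambda <= 0 || K <= 0) stopf("'lambda' and 'K' must be > 0")
  K * m * n * exp(-lambda * raw_score)
}

#' Run one alignment job
#'
#' Aligns every query ORF against the subject ORF set and returns, for each
#' (query, subject) pair, at most its single best-scoring local alignment
#' with e-value at most `params$evalue_keep`. Two backends are available:
#' `"builtin"`, a k-mer-seeded banded affine local aligner compiled into the
#' package (deterministic, always available, e-values approximate), and
#' `"blastn"`, which shells out to NCBI `makeblastdb`/`blastn`.
#'
#' @param job a row of [plan_jobs()] output (or a list with elements
#'   `query_genome`, `subject_genome`, `purpose`).
#' @param query,subject [orf_set] objects; identical for self jobs.
#' @param params an [align_params] object.
#' @param backend `"builtin"` or `"blastn"`.
#' @return A hit-table data.frame with columns `query_genome`,
#'   `subject_genome`, `query_id`, `subject_id`, `evalue`, `pident`,
#'   `pgaps`, `aln_len`, `score`, ordered lexicographically by
#'   (`query_id`, `subject_id`).
#' @export
run_backend <- function(job, query, subject, params = align_params(),
                        backend = c("builtin", "blastn")) {
  backend <- match.arg(backend)
  stopifnot(inherits(query, "orf_set"), inherits(subject, "orf_set"))
  if (length(query) == 0L) stopf("empty query ORF set")
  if (length(subject) == 0L) stopf("empty subject ORF set")
  if (!is.null(job)) {
    if (job$query_genome != query$genome_label ||
        job$subject_genome != subject$genome_label) {
      stopf("job genome labels (%s -> %s) do not match the supplied sets",
            job$query_genome, job$subject_genome)
    }
  }
  hits <- switch(backend,
                 builtin = .run_builtin(query, subject, params),
                 blastn = .run_blastn(query, subject, params))
  hits <- hits[hits$evalue <= params$evalue_keep, , drop = FALSE]
  hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
}

## ---- built-in backend -----------------------------------------------------

## k-mer position table of a character vector of sequences
.kmer_table <- function(txt, ids, k) {
  keep <- nchar(txt) >= k
  if (!any(keep)) {
    return(data.table::data.table(kmer = character(0), id = character(0),
                                  pos = integer(0)))
  }
  pieces <- lapply(which(keep), function(i) {
    L <- nchar(txt[i])
    pos <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(txt[i], pos, pos + k - 1L),
                           id = ids[i], pos = pos)
  })
  data.table::rbindlist(pieces)
}

.run_builtin <- function(query, subject, params) {
  qg <- query$genome_label
  sg <- subject$genome_label
  self_job <- identical(qg, sg)
  qtxt <- as.character(query$seqs)
  stxt <- as.character(subject$seqs)
  qids <- names(qtxt)
  sids <- names(stxt)
  n_space <- sum(nchar(stxt))

  st <- .kmer_table(stxt, sids, params$k)
  data.table::setnames(st, c("kmer", "sid", "spos"))
  data.table::setkey(st, kmer)

  cand_for <- function(qt) {
    if (nrow(qt) == 0L || nrow(st) == 0L) return(NULL)
    data.table::setnames(qt, c("kmer", "qid", "qpos"))
    jn <- st[qt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(jn) == 0L) return(NULL)
    ## cheap pre-filter on *distinct* shared k-mers: random collisions and
    ## repeated words create a sea of useless groups; drop them before
    ## computing any per-group statistics
    cnt <- unique(jn, by = c("qid", "sid", "kmer"))[, .N, by = .(qid, sid)]
    cnt <- cnt[N >= params$min_seeds]
    if (nrow(cnt) == 0L) return(NULL)
    jn <- jn[cnt[, .(qid, sid)], on = c("qid", "sid")]
    jn[, diag := spos - qpos]
    ## n_seeds counts co-diagonal seeds (the largest single-diagonal run):
    ## random k-mer collisions scatter across diagonals, true homology
    ## concentrates on few. The trimmed diagonal range keeps spurious
    ## off-diagonal seeds from blowing the band up to its cap.
    jn[, {
      ds <- sort.int(diag)
      n <- length(ds)
      list(n_seeds = max(rle(ds)$lengths),
           d_lo = ds[max(1L, as.integer(ceiling(0.1 * n)))],
           d_hi = ds[as.integer(ceiling(0.9 * n))],
           d_mid = ds[(n + 1L) %/% 2L])
    }, by = .(qid, sid)]
  }

  qt_fwd <- .kmer_table(qtxt, qids, params$k)
  cands <- cand_for(qt_fwd)
  if (!is.null(cands)) cands[, strand := "+"]
  if (params$both_strands) {
    rtxt <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(qtxt)))
    names(rtxt) <- qids
    cr <- cand_for(.kmer_table(rtxt, qids, params$k))
    if (!is.null(cr)) {
      cr[, strand := "-"]
      cands <- data.table::rbindlist(list(cands, cr))
    }
  } else {
    rtxt <- NULL
  }

  if (is.null(cands) || nrow(cands) == 0L) {
    cands <- data.table::data.table(qid = character(0), sid = character(0),
                                    n_seeds = integer(0), d_lo = integer(0),
                                    d_hi = integer(0), d_mid = integer(0),
                                    strand = character(0))
  }
  cands <- cands[n_seeds >= params$min_seeds |
                   (self_job & qid == sid & strand == "+")]
  ## the identity self-hit must always be present in a self job
  if (self_job) {
    missing_self <- setdiff(qids, cands[qid == sid & strand == "+"]$qid)
    if (length(missing_self)) {
      cands <- data.table::rbindlist(list(
        cands,
        data.table::data.table(qid = missing_self, sid = missing_self,
                               n_seeds = 0L, d_lo = 0L, d_hi = 0L,
                               d_mid = 0L, strand = "+")))
    }
  }
  if (nrow(cands) == 0L) return(empty_hit_table(qg, sg))

  res <- vector("list", nrow(cands))
  qi <- match(cands$qid, qids)
  si <- match(cands$sid, sids)
  for (i in seq_len(nrow(cands))) {
    qs <- if (cands$strand[i] == "+") qtxt[[qi[i]]] else rtxt[[qi[i]]]
    ## band around the seed diagonal range, clipped to band_max
    lo <- cands$d_lo[i] - params$band_pad
    hi <- cands$d_hi[i] + params$band_pad
    if (hi - lo + 1L > params$band_max) {
      half <- params$band_max %/% 2L
      lo <- cands$d_mid[i] - half
      hi <- cands$d_mid[i] + half
    }
    a <- banded_local_align(qs, stxt[[si[i]]], lo, hi,
                            params$match, params$mismatch,
                            params$gap_open, params$gap_extend)
    res[[i]] <- a
  }
  mat <- do.call(rbind, res)
  out <- data.table::data.table(
    query_id = cands$qid, subject_id = cands$sid, strand = cands$strand,
    score = as.numeric(mat[, 1L]), aln_len = mat[, 2L],
    n_ident = mat[, 3L], n_gap = mat[, 4L])
  out <- out[score > 0]
  if (nrow(out) == 0L) return(empty_hit_table(qg, sg))
  ## best strand per (query, subject): higher score, '+' on ties
  data.table::setorder(out, query_id, subject_id, -score, strand)
  out <- out[!duplicated(paste(out$query_id, out$subject_id))]
  qlen <- nchar(qtxt)
  out[, evalue := evalue_from_score(score, qlen[query_id], n_space,
                                    params$lambda, params$K)]
  data.frame(query_genome = qg, subject_genome = sg,
             query_id = out$query_id, subject_id = out$subject_id,
             evalue = out$evalue,
             pident = 100 * out$n_ident / out$aln_len,
             pgaps = 100 * out$n_gap / out$aln_len,
             aln_len = as.integer(out$aln_len), score = out$score,
             stringsAsFactors = FALSE)
}

## ---- external blastn backend ----------------------------------------------

.run_blastn <- function(query, subject, params) {
  blastn <- Sys.which("blastn")
  makedb <- Sys.which("makeblastdb")
  if (!nzchar(blastn) || !nzchar(makedb)) {
    stopf(paste("blastn/makeblastdb not found on PATH;",
                "use backend = 'builtin'"))
  }
  td <- tempfile("blastjob")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "query.fa")
  sf <- file.path(td, "subject.fa")
  of <- file.path(td, "hits.tsv")
  write_orf_fasta(query, qf)
  write_orf_fasta(subject, sf)
  st1 <- system2(makedb, c("-in", sf, "-dbtype", "nucl"),
                 stdout = FALSE, stderr = FALSE)
  if (st1 != 0L) stopf("makeblastdb failed (exit %d)", st1)
  fmt <- paste("6 qseqid sseqid pident length mismatch gapopen",
               "qstart qend sstart send evalue bitscore gaps")
  args <- c("-query", qf, "-db", sf, "-task", "blastn",
            "-evalue", format(params$evalue_keep),
            "-reward", params$match, "-penalty", params$mismatch,
            "-gapopen", params$gap_open, "-gapextend", params$gap_extend,
            "-max_hsps", "1", "-max_target_seqs", "5000",
            "-dust", "no", "-soft_masking", "false",
            "-strand", if (params$both_strands) "both" else "plus",
            "-outfmt", shQuote(fmt), "-out", of)
  st2 <- system2(blastn, args, stdout = FALSE, stderr = FALSE)
  if (st2 != 0L) stopf("blastn failed (exit %d)", st2)
  hits <- parse_tabular_hits(of, query$genome_label, subject$genome_label)
  ## defensive: keep the best line per pair even if several slipped through
  o <- order(hits$query_id, hits$subject_id, hits$evalue, -hits$score)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(paste(hits$query_id, hits$subject_id)), , drop = FALSE]
}

#' Parse BLAST tabular output into a hit table
#'
#' Reads BLAST outfmt-6-style tabular output (12 standard columns, or the
#' extended 13-column dialect ending in a gap count; `#` comment lines are
#' ignored). Percent identity comes from column 3, alignment length from
#' column 4, e-value from column 11 and (bit)score from column 12. The gap
#' percentage is computed as `gaps / aln_len * 100` from the 13th column when
#' present; the 6th standard column counts gap *openings*, not gap columns,
#' and is never used for it. With 12 columns `pgaps` is `NA` (unavailable).
#'
#' @param path file path.
#' @param query_genome,subject_genome genome labels recorded on the table.
#' @return A hit-table data.frame (see [run_backend()]), rows in input order.
#' @export
parse_tabular_hits <- function(path, query_genome, subject_genome) {
  if (!file.exists(path)) stopf("hit file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(empty_hit_table(query_genome, subject_genome))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc != 12L & nc != 13L)) {
    bad <- which(keep)[which(nc != 12L & nc != 13L)[1L]]
    stopf("line %d: expected 12 or 13 tab-separated columns, found %d",
          bad, nc[which(keep) == bad])
  }
  get <- function(j) vapply(rows, `[`, character(1), j)
  aln_len <- as.integer(get(4L))
  pgaps <- rep(NA_real_, length(rows))
  has13 <- nc == 13L
  if (any(has13)) {
    gaps <- suppressWarnings(as.numeric(vapply(rows[has13], `[`,
                                               character(1), 13L)))
    pgaps[has13] <- 100 * gaps / aln_len[has13]
  }
  data.frame(query_genome = query_genome, subject_genome = subject_genome,
             query_id = get(1L), subject_id = get(2L),
             evalue = as.numeric(get(11L)), pident = as.numeric(get(3L)),
             pgaps = pgaps, aln_len = aln_len,
             score = as.numeric(get(12L)), stringsAsFactors = FALSE)
}
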