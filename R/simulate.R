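#' Simulation configuration for synthetic hybrid genomes
#'
#' Defines the evolutionary scenario emulated by the generator: a set of
#' ancestor ORFs; two (or more) parents diverged from it by independent
#' per-site substitution plus occasional small-scale duplications; and an
#' aneuploid hybrid that samples allele copies from the parents (per-parent
#' ploidy), with copy losses, slight post-hybridization divergence, and
#' post-hybridization duplications. Every hybrid ORF's true origin is
#' recorded.
#'
#' Defaults describe a lager-yeast-like scenario: 500 ancestral genes of
#' around 1 kb, 10% divergence on each parent branch, one chromosome set
#' from parent A and two from parent B (approximately triploid), 10% copy
#' loss, 0.5% post-hybridization divergence, and a few percent small-scale
#' duplications per branch.
#'
#' @param n_genes number of ancestor genes (>= 1).
#' @param len_mean,len_sd gene length distribution in bases (normal,
#'   truncated at >= 150 so seed words always fit).
#' @param gc GC fraction of ancestral sequence.
#' @param div_parent per-site substitution probability on each parent branch.
#' @param dup_rate_parent per-gene probability of a small-scale duplication
#'   in a parent.
#' @param ploidy named integer vector: hybrid copy count per parent.
#' @param loss_rate per-copy probability of loss in the hybrid.
#' @param div_posthyb per-site substitution on each hybrid copy after
#'   hybridization; should be well below `div_parent` or parental origin
#'   becomes unidentifiable (warned).
#' @param dup_rate_hybrid per-gene post-hybridization duplication
#'   probability.
#' @param seed integer random seed; every stage derives its own stream from
#'   it, so output is fully deterministic.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, len_mean = 1000, len_sd = 300,
                       gc = 0.40, div_parent = 0.10,
                       dup_rate_parent = 0.02,
                       ploidy = c(parentA = 1L, parentB = 2L),
                       loss_rate = 0.10, div_posthyb = 0.005,
                       dup_rate_hybrid = 0.02, seed = 42L) {
  if (n_genes < 1L) stopf("'n_genes' must be >= 1")
  probs <- c(gc = gc, div_parent = div_parent,
             dup_rate_parent = dup_rate_parent, loss_rate = loss_rate,
             div_posthyb = div_posthyb, dup_rate_hybrid = dup_rate_hybrid)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stopf("'%s' must be in [0, 1]", names(probs)[bad][1L])
  if (is.null(names(ploidy)) || any(!nzchar(names(ploidy)))) {
    stopf("'ploidy' must be named by parent label")
  }
  if (any(ploidy < 1L)) stopf("ploidy copy counts must be >= 1")
  if (div_posthyb >= div_parent && div_parent > 0) {
    warning("div_posthyb >= div_parent: parental origin of hybrid copies ",
            "may not be identifiable", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), len_mean = len_mean,
                 len_sd = len_sd, gc = gc, div_parent = div_parent,
                 dup_rate_parent = dup_rate_parent, ploidy = ploidy,
                 loss_rate = loss_rate, div_posthyb = div_posthyb,
                 dup_rate_hybrid = dup_rate_hybrid,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## per-site substitution, uniform over the three alternative bases
.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- which(stats::runif(length(ch)) < rate)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    ch[idx] <- vapply(ch[idx], function(b) {
      sample(bases[bases != b], 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

#' Simulate an ancestral ORF set
#'
#' Generates `n_genes` i.i.d. nucleotide sequences at the configured GC
#' content, with lengths drawn from a normal distribution truncated at
#' 150 nt.
#'
#' @param config a [sim_config].
#' @return An [orf_set] labelled `"ancestor"` with ids `anc0001`, ...
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    lens <- pmax(150L, as.integer(round(
      stats::rnorm(config$n_genes, config$len_mean, config$len_sd))))
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("anc%04d", seq_len(config$n_genes))
    orf_set(seqs, "ancestor")
  })
}

#' Evolve one parent genome from the ancestor
#'
#' Applies independent per-site substitution at rate `div_parent` to every
#' ancestor gene, then duplicates a random subset of genes (probability
#' `dup_rate_parent` per gene); duplicates receive one extra substitution
#' pass so they are distinguishable from their template.
#'
#' @param ancestor ancestral [orf_set].
#' @param label genome label of the parent.
#' @param div_parent per-site substitution probability.
#' @param dup_rate_parent per-gene duplication probability.
#' @param seed integer seed for this branch.
#' @return A list with elements `orfs` (the parent [orf_set], gene ids
#'   `<label>_<anc_id>` plus `_dup` copies) and `truth` (data.frame
#'   `gene_id`, `template_id`, `anc_id`, `is_duplicate`).
#' @export
diverge_parent <- function(ancestor, label, div_parent, dup_rate_parent,
                           seed) {
  stopifnot(inherits(ancestor, "orf_set"))
  with_seed(seed, {
    anc_ids <- orf_ids(ancestor)
    base <- vapply(as.character(ancestor$seqs), .mutate_seq, character(1),
                   rate = div_parent, USE.NAMES = FALSE)
    ids <- paste0(label, "_", anc_ids)
    truth <- data.frame(gene_id = ids, template_id = NA_character_,
                        anc_id = anc_ids, is_duplicate = FALSE,
                        stringsAsFactors = FALSE)
    dup <- which(stats::runif(length(ids)) < dup_rate_parent)
    if (length(dup)) {
      dseq <- vapply(base[dup], .mutate_seq, character(1),
                     rate = div_parent, USE.NAMES = FALSE)
      dids <- paste0(ids[dup], "_dup")
      base <- c(base, dseq)
      truth <- rbind(truth, data.frame(
        gene_id = dids, template_id = ids[dup], anc_id = anc_ids[dup],
        is_duplicate = TRUE, stringsAsFactors = FALSE))
      ids <- c(ids, dids)
    }
    list(orfs = orf_set(stats::setNames(base, ids), label), truth = truth)
  })
}

#' Assemble the aneuploid hybrid genome
#'
#' For every parent gene and every ploidy copy, includes the copy unless it
#' is lost (probability `loss_rate`), applies post-hybridization
#' substitutions, and finally duplicates a random subset of hybrid ORFs
#' (probability `dup_rate_hybrid`, one extra substitution pass). Hybrid ids
#' are fresh (`hyb00001`, ...).
#'
#' @param parents named list, one element per parent: either the output of
#'   [diverge_parent()] (preferred, so inherited paralogs are labelled in
#'   the truth) or a bare [orf_set].
#' @param ploidy named integer vector of copy counts per parent label.
#' @param loss_rate per-copy loss probability.
#' @param div_posthyb per-site post-hybridization substitution probability.
#' @param dup_rate_hybrid per-ORF post-hybridization duplication probability.
#' @param seed integer seed.
#' @return A list with elements `orfs` (hybrid [orf_set]) and `truth`
#'   (data.frame `hybrid_id`, `source_parent`, `source_gene`, `source_anc`,
#'   `origin_class` in `{inherited-ortholog, inherited-paralog,
#'   posthyb-duplicate}`).
#' @export
make_hybrid <- function(parents, ploidy, loss_rate, div_posthyb,
                        dup_rate_hybrid, seed) {
  if (!length(parents)) stopf("'parents' must be non-empty")
  norm <- lapply(parents, function(p) {
    if (inherits(p, "orf_set")) list(orfs = p, truth = NULL) else p
  })
  labs <- vapply(norm, function(p) p$orfs$genome_label, character(1))
  if (is.null(names(parents))) names(norm) <- labs
  if (!all(names(norm) %in% names(ploidy))) {
    stopf("'ploidy' must name every parent label")
  }
  with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    counter <- 0L
    for (p in names(norm)) {
      po <- norm[[p]]$orfs
      pt <- norm[[p]]$truth
      gseq <- as.character(po$seqs)
      for (g in orf_ids(po)) {
        is_dup <- !is.null(pt) && isTRUE(pt$is_duplicate[pt$gene_id == g])
        anc <- if (!is.null(pt)) pt$anc_id[pt$gene_id == g] else NA_character_
        for (cp in seq_len(ploidy[[p]])) {
          if (stats::runif(1L) < loss_rate) next
          counter <- counter + 1L
          hid <- sprintf("hyb%05d", counter)
          seqs[hid] <- .mutate_seq(gseq[[g]], div_posthyb)
          truth[[hid]] <- data.frame(
            hybrid_id = hid, source_parent = p, source_gene = g,
            source_anc = anc,
            origin_class = if (is_dup) "inherited-paralog"
                           else "inherited-ortholog",
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth) || nrow(truth) == 0L) {
      warning("all hybrid gene copies were lost; hybrid genome is empty",
              call. = FALSE)
      return(list(orfs = NULL,
                  truth = data.frame(hybrid_id = character(0),
                                     source_parent = character(0),
                                     source_gene = character(0),
                                     source_anc = character(0),
                                     origin_class = character(0))))
    }
    ## post-hybridization duplications
    dup <- which(stats::runif(length(seqs)) < dup_rate_hybrid)
    if (length(dup)) {
      for (i in dup) {
        counter <- counter + 1L
        hid <- sprintf("hyb%05d", counter)
        tmpl <- names(seqs)[i]
        seqs[hid] <- .mutate_seq(seqs[[i]], div_posthyb)
        row <- truth[truth$hybrid_id == tmpl, , drop = FALSE]
        row$hybrid_id <- hid
        row$origin_class <- "posthyb-duplicate"
        truth <- rbind(truth, row)
      }
    }
    rownames(truth) <- NULL
    list(orfs = orf_set(seqs, "hybrid"), truth = truth)
  })
}

#' Simulate a complete parent/hybrid dataset with ground truth
#'
#' Convenience wrapper running [simulate_ancestor()], [diverge_parent()]
#' for each parent in `config$ploidy`, and [make_hybrid()], with
#' per-stage seeds derived from `config$seed`.
#'
#' @param config a [sim_config].
#' @return A list with elements `config`, `ancestor`, `parents` (named list
#'   of [orf_set]), `parent_truth` (named list), `hybrid` ([orf_set]),
#'   `truth` (hybrid origin table) and `cross_truth` (data.frame of
#'   true cross-parent ortholog gene pairs, 2-parent case only).
#' @export
simulate_hybrid_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  anc <- simulate_ancestor(config)
  labs <- names(config$ploidy)
  par <- lapply(seq_along(labs), function(i) {
    diverge_parent(anc, labs[i], config$div_parent,
                   config$dup_rate_parent,
                   derive_seed(config$seed, 10L + i))
  })
  names(par) <- labs
  hyb <- make_hybrid(par, config$ploidy, config$loss_rate,
                     config$div_posthyb, config$dup_rate_hybrid,
                     derive_seed(config$seed, 100L))
  cross <- NULL
  if (length(labs) == 2L) {
    tA <- par[[1L]]$truth
    tB <- par[[2L]]$truth
    a <- tA[!tA$is_duplicate, c("gene_id", "anc_id")]
    b <- tB[!tB$is_duplicate, c("gene_id", "anc_id")]
    cross <- merge(a, b, by = "anc_id", suffixes = c("_a", "_b"))
    cross <- data.frame(id_a = cross$gene_id_a, id_b = cross$gene_id_b,
                        anc_id = cross$anc_id, stringsAsFactors = FALSE)
  }
  list(config = config, ancestor = anc,
       parents = lapply(par, `[[`, "orfs"),
       parent_truth = lapply(par, `[[`, "truth"),
       hybrid = hyb$orfs, truth = hyb$truth, cross_truth = cross)
}

#' Score pipeline recovery against simulator ground truth
#'
#' Compares an assignment table with the simulator's origin table.
#' Precision is the fraction of ASSIGNED ORFs whose predicted parent matches
#' the true source parent; recall is the fraction of decidable true-origin
#' ORFs recovered with the correct parent. A locus is *decidable* when its
#' source gene's sequence is not identically present in another parent
#' (identical parental sequences make the origin unknowable in principle).
#'
#' @param assignments assignment data.frame over the hybrid ORFs.
#' @param truth simulator truth table (from [make_hybrid()]).
#' @param parents named list of parent [orf_set]s (used for the
#'   decidability check).
#' @return A list with elements `precision`, `recall` (`NA` when
#'   undefined), `per_parent` (data.frame), `n_assigned`, `n_decidable`,
#'   `copy_number` (per-gene predicted vs true copies with `error`),
#'   `copy_exact_frac`.
#' @export
score_recovery <- function(assignments, truth, parents) {
  if (!setequal(assignments$hybrid_id, truth$hybrid_id)) {
    stopf("assignments and truth cover different hybrid id sets")
  }
  m <- merge(assignments, truth, by = "hybrid_id")

  ## decidability: is the true source sequence unique to its parent?
  seq_by_parent <- lapply(parents, function(p) as.character(p$seqs))
  src_seq <- mapply(function(p, g) seq_by_parent[[p]][[g]],
                    m$source_parent, m$source_gene)
  tied <- vapply(seq_along(src_seq), function(i) {
    others <- setdiff(names(parents), m$source_parent[i])
    any(vapply(others, function(o) {
      src_seq[[i]] %in% seq_by_parent[[o]]
    }, logical(1)))
  }, logical(1))

  assigned <- m$category == "ASSIGNED"
  correct <- assigned & m$parent_label == m$source_parent
  decidable <- !tied
  precision <- if (any(assigned)) sum(correct) / sum(assigned) else NA_real_
  recall <- if (any(decidable)) {
    sum(correct & decidable) / sum(decidable)
  } else NA_real_

  per_parent <- do.call(rbind, lapply(sort(unique(m$source_parent)),
                                      function(p) {
    sel_t <- m$source_parent == p & decidable
    sel_a <- assigned & !is.na(m$parent_label) & m$parent_label == p
    data.frame(parent = p,
               precision = if (any(sel_a)) {
                 sum(correct[sel_a]) / sum(sel_a)
               } else NA_real_,
               recall = if (any(sel_t)) {
                 sum(correct & decidable & m$source_parent == p) / sum(sel_t)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))

  true_cn <- table(m$source_gene)
  pred <- copy_numbers(assignments)
  genes <- sort(unique(c(names(true_cn), pred$parental_gene_id)))
  cn <- data.frame(
    parental_gene_id = genes,
    true_copies = as.integer(true_cn[genes]),
    predicted_copies = pred$copy_number[match(genes, pred$parental_gene_id)],
    stringsAsFactors = FALSE)
  cn$true_copies[is.na(cn$true_copies)] <- 0L
  cn$predicted_copies[is.na(cn$predicted_copies)] <- 0L
  cn$error <- cn$predicted_copies - cn$true_copies

  list(precision = precision, recall = recall, per_parent = per_parent,
       n_assigned = sum(assigned), n_decidable = sum(decidable),
       copy_number = cn, copy_exact_frac = mean(cn$error == 0L))
}
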