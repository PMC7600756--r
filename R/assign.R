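## outcome categories of the per-ORF classification
.categories <- c("ASSIGNED", "AMBIGUOUS_EQUAL_IDENTITY",
                 "SUBTHRESHOLD_IDENTITY", "NO_PREDICTION")

#' Assign a parental allele to every hybrid ORF
#'
#' Each hybrid ORF falls into exactly one of four mutually exclusive
#' categories:
#' \describe{
#'   \item{ASSIGNED}{a 1:1 ortholog exists in at least one parent and a
#'     unique parent has the strictly highest ortholog identity; that
#'     parent's gene is the predicted parental allele.}
#'   \item{AMBIGUOUS_EQUAL_IDENTITY}{two or more parents tie for the highest
#'     ortholog identity (typical of extremely conserved sequences such as
#'     tRNAs, identical between parents).}
#'   \item{SUBTHRESHOLD_IDENTITY}{no ortholog survived, and the only saved
#'     best hits failed the identity filter (identity <= `identity_min`).}
#'   \item{NO_PREDICTION}{no saved hit in any parent, or a best hit passed
#'     the identity filter but was not reciprocal -- reciprocity failure
#'     yields no predicted allele at all.}
#' }
#' Identity ties are declared at the reported precision of the alignment
#' backend (`digits` decimals, default 2), not on full sequence equality;
#' pass `digits = Inf` for exact-value comparison.
#'
#' @param ortholog_sets named list (one element per parent label, 2-4) of
#'   BBH pair data.frames from [find_orthologs()], each with the hybrid as
#'   the `a` side.
#' @param subthreshold_ids named list (same parent labels) of character
#'   vectors of hybrid ids whose best hit failed the identity filter.
#' @param all_hybrid_ids character vector of every hybrid ORF id.
#' @param nonreciprocal_ids optional named list of hybrid ids whose best hit
#'   passed the identity filter but failed reciprocity; such ORFs fall to
#'   NO_PREDICTION rather than SUBTHRESHOLD_IDENTITY even when another
#'   parent held a subthreshold best hit.
#' @param identity_min identity threshold in percent; ASSIGNED implies the
#'   winning identity exceeds it.
#' @param digits decimal places at which identities are compared for ties.
#' @return A data.frame with one row per hybrid ORF, columns `hybrid_id`,
#'   `category`, `parent_label`, `parental_gene_id`, `pident`, `origin`
#'   (`"ortholog"` here; see [propagate_group_alleles()]), `tied_parents`.
#' @export
assign_parental_alleles <- function(ortholog_sets, subthreshold_ids,
                                    all_hybrid_ids, identity_min = 80,
                                    digits = 2, nonreciprocal_ids = NULL) {
  np <- length(ortholog_sets)
  if (np < 2L || np > 4L) stopf("2 to 4 parental ortholog sets expected")
  labs <- names(ortholog_sets)
  if (is.null(labs) || any(!nzchar(labs))) {
    stopf("'ortholog_sets' must be named by parent label")
  }
  for (p in labs) {
    ids <- ortholog_sets[[p]]$id_a
    unknown <- setdiff(ids, all_hybrid_ids)
    if (length(unknown)) {
      stopf("hybrid id %s in ortholog set '%s' is absent from all_hybrid_ids",
            unknown[1L], p)
    }
  }
  rnd <- function(x) if (is.infinite(digits)) x else round(x, digits)

  pid <- matrix(NA_real_, length(all_hybrid_ids), np,
                dimnames = list(all_hybrid_ids, labs))
  gene <- matrix(NA_character_, length(all_hybrid_ids), np,
                 dimnames = list(all_hybrid_ids, labs))
  for (p in labs) {
    s <- ortholog_sets[[p]]
    if (nrow(s)) {
      pid[s$id_a, p] <- s$pident
      gene[s$id_a, p] <- s$id_b
    }
  }
  sub_any <- all_hybrid_ids %in% unique(unlist(subthreshold_ids))
  nonrec_any <- all_hybrid_ids %in% unique(unlist(nonreciprocal_ids))

  category <- character(length(all_hybrid_ids))
  parent <- rep(NA_character_, length(all_hybrid_ids))
  pgene <- rep(NA_character_, length(all_hybrid_ids))
  ppid <- rep(NA_real_, length(all_hybrid_ids))
  tied <- rep(NA_character_, length(all_hybrid_ids))
  for (i in seq_along(all_hybrid_ids)) {
    v <- pid[i, ]
    if (all(is.na(v))) {
      category[i] <- if (sub_any[i] && !nonrec_any[i]) {
        "SUBTHRESHOLD_IDENTITY"
      } else "NO_PREDICTION"
      next
    }
    r <- rnd(v)
    mx <- max(r, na.rm = TRUE)
    winners <- labs[!is.na(r) & r == mx]
    if (length(winners) == 1L) {
      category[i] <- "ASSIGNED"
      parent[i] <- winners
      pgene[i] <- gene[i, winners]
      ppid[i] <- pid[i, winners]
    } else {
      category[i] <- "AMBIGUOUS_EQUAL_IDENTITY"
      tied[i] <- paste(winners, collapse = ",")
    }
  }
  data.frame(hybrid_id = all_hybrid_ids, category = category,
             parent_label = parent, parental_gene_id = pgene, pident = ppid,
             origin = ifelse(category == "ASSIGNED", "ortholog",
                             NA_character_),
             tied_parents = tied, stringsAsFactors = FALSE)
}

#' Propagate parental alleles through hybrid paralog links
#'
#' A hybrid ORF that failed the 1:1 reciprocity test (because a sibling copy
#' of the same gene "won" the reciprocal best hit) is still linked to its
#' siblings in the hybrid self-alignment. This final annotation step gives
#' every unpredicted hybrid ORF the parental allele of its closest
#' (highest-identity) assigned paralog partner, iterating so that chains of
#' copies resolve. Propagated rows keep category `ASSIGNED` but are marked
#' `origin = "homolog-group"`; only `NO_PREDICTION` ORFs are ever promoted.
#'
#' With three or more copies of one gene, two unassigned copies can be each
#' other's *mutual* best hit, so the BBH pair graph alone never reaches the
#' assigned copy; passing the full self-alignment hit table (recommended,
#' and what [run_pipeline()] does) uses every paralog link instead.
#'
#' @param assignments output of [assign_parental_alleles()].
#' @param hybrid_self_links either the hybrid self-alignment hit table
#'   (columns `query_id`, `subject_id`, `pident`) or a data.frame of
#'   self-BBH pairs (columns `id_a`, `id_b`, `pident`).
#' @param max_rounds safety cap on propagation passes.
#' @return The updated assignment data.frame.
#' @export
propagate_group_alleles <- function(assignments, hybrid_self_links,
                                    max_rounds = 100L) {
  if (nrow(hybrid_self_links) == 0L) return(assignments)
  ## normalise to an undirected partner list with link identities
  if (all(c("query_id", "subject_id") %in% names(hybrid_self_links))) {
    h <- hybrid_self_links[hybrid_self_links$query_id !=
                             hybrid_self_links$subject_id, , drop = FALSE]
    e <- rbind(
      data.frame(id = h$query_id, partner = h$subject_id,
                 link_pident = h$pident, stringsAsFactors = FALSE),
      data.frame(id = h$subject_id, partner = h$query_id,
                 link_pident = h$pident, stringsAsFactors = FALSE))
  } else {
    e <- rbind(
      data.frame(id = hybrid_self_links$id_a,
                 partner = hybrid_self_links$id_b,
                 link_pident = hybrid_self_links$pident,
                 stringsAsFactors = FALSE),
      data.frame(id = hybrid_self_links$id_b,
                 partner = hybrid_self_links$id_a,
                 link_pident = hybrid_self_links$pident,
                 stringsAsFactors = FALSE))
  }
  e <- e[!duplicated(paste(e$id, e$partner)), , drop = FALSE]
  e <- e[order(e$id, -e$link_pident, e$partner), , drop = FALSE]
  rownames(assignments) <- assignments$hybrid_id
  for (round in seq_len(max_rounds)) {
    todo <- assignments$hybrid_id[assignments$category == "NO_PREDICTION"]
    sub <- e[e$id %in% todo, , drop = FALSE]
    if (nrow(sub) == 0L) break
    donor_ok <- assignments[sub$partner, "category"] == "ASSIGNED"
    sub <- sub[donor_ok, , drop = FALSE]
    if (nrow(sub) == 0L) break
    sub <- sub[!duplicated(sub$id), , drop = FALSE]  # best donor per ORF
    assignments[sub$id, "category"] <- "ASSIGNED"
    assignments[sub$id, "parent_label"] <-
      assignments[sub$partner, "parent_label"]
    assignments[sub$id, "parental_gene_id"] <-
      assignments[sub$partner, "parental_gene_id"]
    assignments[sub$id, "pident"] <- assignments[sub$partner, "pident"]
    assignments[sub$id, "origin"] <- "homolog-group"
  }
  rownames(assignments) <- NULL
  assignments
}

#' Category summary of an assignment run
#'
#' Tallies the classification into its output contract: one count of
#' assigned alleles per parent, the ambiguous / subthreshold / no-prediction
#' counts, the total ORF number, and the number of distinct paralogs. The
#' counts partition the ORF set: per-parent assigned + ambiguous +
#' subthreshold + no-prediction equals the total.
#'
#' Because "number of different paralogs" admits several readings, three
#' counts are reported side by side: `distinct_paralogs` (hybrid ORFs that
#' are members of at least one hybrid homolog group -- the primary
#' definition), `paralog_groups` and `paralog_pairs`.
#'
#' @param assignments assignment data.frame covering every hybrid ORF once.
#' @param hybrid_groups a `homolog_groups` object over hybrid ORFs
#'   (or `NULL`).
#' @param label run label used for the summary column.
#' @return A data.frame with columns `metric`, `value`.
#' @export
classify_summary <- function(assignments, hybrid_groups = NULL,
                             label = "run") {
  if (anyDuplicated(assignments$hybrid_id)) {
    stopf("hybrid ORF %s is assigned more than once",
          assignments$hybrid_id[duplicated(assignments$hybrid_id)][1L])
  }
  if (!all(assignments$category %in% .categories)) {
    stopf("unknown category '%s'",
          setdiff(assignments$category, .categories)[1L])
  }
  parents <- sort(unique(stats::na.omit(assignments$parent_label)))
  per_parent <- vapply(parents, function(p) {
    sum(assignments$category == "ASSIGNED" &
          assignments$parent_label == p, na.rm = TRUE)
  }, integer(1))
  amb <- sum(assignments$category == "AMBIGUOUS_EQUAL_IDENTITY")
  sub <- sum(assignments$category == "SUBTHRESHOLD_IDENTITY")
  nop <- sum(assignments$category == "NO_PREDICTION")
  total <- nrow(assignments)
  stopifnot(sum(per_parent) + amb + sub + nop == total)
  memb <- if (!is.null(hybrid_groups)) {
    unique(unlist(hybrid_groups, use.names = FALSE))
  } else character(0)
  n_pairs <- if (!is.null(hybrid_groups)) {
    ev <- attr(hybrid_groups, "evidence")
    if (is.data.frame(ev)) nrow(ev) else 0L
  } else 0L
  metrics <- c("total_orfs",
               if (length(parents)) paste0("assigned:", parents),
               "ambiguous_equal_identity", "subthreshold_identity",
               "no_prediction", "distinct_paralogs", "paralog_groups",
               "paralog_pairs")
  values <- c(total, per_parent, amb, sub, nop,
              length(memb), length(hybrid_groups %||% list()), n_pairs)
  out <- data.frame(metric = metrics, value = as.integer(values),
                    stringsAsFactors = FALSE)
  names(out)[2L] <- label
  out
}

#' Copy number of each parental gene in the hybrid
#'
#' Counts, for every parental gene that received at least one assignment,
#' how many hybrid ORFs were assigned to it -- the predicted gene copy
#' number in the (possibly aneuploid) hybrid. Copy numbers sum to the number
#' of ASSIGNED ORFs.
#'
#' @param assignments assignment data.frame
#'   (after optional [propagate_group_alleles()]).
#' @return A data.frame with columns `parental_gene_id`, `parent_label`,
#'   `copy_number`, `hybrid_ids` (comma-separated members), sorted by parent
#'   then gene id.
#' @export
copy_numbers <- function(assignments) {
  a <- assignments[assignments$category == "ASSIGNED", , drop = FALSE]
  if (nrow(a) == 0L) {
    return(data.frame(parental_gene_id = character(0),
                      parent_label = character(0), copy_number = integer(0),
                      hybrid_ids = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(a$parent_label, a$parental_gene_id, sep = "\r")
  sp <- split(a$hybrid_id, key)
  parts <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(
    parental_gene_id = vapply(parts, `[`, character(1), 2L),
    parent_label = vapply(parts, `[`, character(1), 1L),
    copy_number = lengths(sp),
    hybrid_ids = vapply(sp, function(v) paste(sort(v), collapse = ","),
                        character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$parent_label, out$parental_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Homolog groups in the hybrid genome
#'
#' Builds a graph over hybrid ORFs from up to three evidence layers and
#' returns its connected components as homolog groups:
#' \describe{
#'   \item{self}{hybrid self-BBH paralog pairs;}
#'   \item{parent-paralog}{edges between hybrid ORFs whose assigned parental
#'     genes form a paralog pair within one parent (inherited paralogs);}
#'   \item{cross-ortholog}{edges between hybrid ORFs whose assigned parental
#'     genes are cross-parent 1:1 orthologs (both parental alleles of one
#'     ancestral gene retained).}
#' }
#'
#' @param hybrid_self_pairs hybrid self-BBH pairs.
#' @param parent_self_pairs named list (by parent label) of parent self-BBH
#'   paralog pairs, or `NULL`.
#' @param cross_parent_pairs cross-parent ortholog pairs, or `NULL`.
#' @param assignments assignment data.frame.
#' @param layers subset of `c("self", "parent-paralog", "cross-ortholog")`.
#' @return A `homolog_groups` object over hybrid ORF ids; the flat
#'   annotated membership (with each member's assigned parent and gene) is
#'   in attribute `annotation`.
#' @export
hybrid_homolog_groups <- function(hybrid_self_pairs,
                                  parent_self_pairs = NULL,
                                  cross_parent_pairs = NULL,
                                  assignments = NULL,
                                  layers = c("self", "parent-paralog",
                                             "cross-ortholog")) {
  layers <- match.arg(layers, several.ok = TRUE)
  edges <- list()
  if ("self" %in% layers && !is.null(hybrid_self_pairs) &&
      nrow(hybrid_self_pairs)) {
    edges$self <- hybrid_self_pairs[, c("id_a", "id_b")]
  }
  gene_edges <- function(pairs) {
    ## lift parental-gene pairs to edges between their assigned hybrid ORFs
    a <- assignments[assignments$category == "ASSIGNED", , drop = FALSE]
    by_gene <- split(a$hybrid_id, a$parental_gene_id)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      ha <- by_gene[[pairs$id_a[i]]]
      hb <- by_gene[[pairs$id_b[i]]]
      if (is.null(ha) || is.null(hb)) return(NULL)
      expand.grid(id_a = ha, id_b = hb, stringsAsFactors = FALSE)
    }))
  }
  if ("parent-paralog" %in% layers && !is.null(parent_self_pairs) &&
      !is.null(assignments)) {
    for (p in names(parent_self_pairs)) {
      pp <- parent_self_pairs[[p]]
      if (!is.null(pp) && nrow(pp)) {
        e <- gene_edges(pp)
        if (!is.null(e)) edges[[paste0("pp_", p)]] <- e
      }
    }
  }
  if ("cross-ortholog" %in% layers && !is.null(cross_parent_pairs) &&
      !is.null(assignments) && nrow(cross_parent_pairs)) {
    e <- gene_edges(cross_parent_pairs)
    if (!is.null(e)) edges$cross <- e
  }
  all_edges <- if (length(edges)) {
    do.call(rbind, unname(edges))
  } else {
    data.frame(id_a = character(0), id_b = character(0),
               stringsAsFactors = FALSE)
  }
  all_edges <- all_edges[all_edges$id_a != all_edges$id_b, , drop = FALSE]
  groups <- merge_into_groups(all_edges)
  if (!is.null(assignments) && length(groups)) {
    memb <- groups_membership(groups)
    idx <- match(memb$member_id, assignments$hybrid_id)
    memb$parent_label <- assignments$parent_label[idx]
    memb$parental_gene_id <- assignments$parental_gene_id[idx]
    attr(groups, "annotation") <- memb
  }
  groups
}

#' Shared-function report for a two-parent hybrid
#'
#' For each cross-parent 1:1 ortholog pair, both parental alleles may have
#' been retained in the hybrid (each gene of the pair received at least one
#' assignment), or only one parent's gene function is represented. Assigned
#' parental genes outside any both-retained pair are counted per parent --
#' the three numbers of a two-set Venn diagram of inherited functions.
#'
#' @param assignments assignment data.frame.
#' @param cross_parent_pairs cross-parent ortholog pairs between exactly the
#'   two parents present in `assignments`.
#' @return A data.frame with columns `metric`
#'   (`<parentA>_only`, `<parentB>_only`, `both_retained_pairs`) and `count`.
#' @export
shared_function_report <- function(assignments, cross_parent_pairs) {
  a <- assignments[assignments$category == "ASSIGNED", , drop = FALSE]
  parents <- sort(unique(stats::na.omit(assignments$parent_label)))
  if (nrow(cross_parent_pairs)) {
    parents <- sort(unique(c(parents, cross_parent_pairs$genome_a[1L],
                             cross_parent_pairs$genome_b[1L])))
  }
  if (length(parents) != 2L) {
    stopf("shared_function_report() requires exactly 2 parents, found %d",
          length(parents))
  }
  assigned_genes <- function(p) {
    unique(a$parental_gene_id[a$parent_label == p])
  }
  gA <- assigned_genes(parents[1L])
  gB <- assigned_genes(parents[2L])
  if (nrow(cross_parent_pairs)) {
    ## orient pairs so that the 'a' member belongs to parents[1]
    swap <- cross_parent_pairs$genome_a != parents[1L]
    pa <- ifelse(swap, cross_parent_pairs$id_b, cross_parent_pairs$id_a)
    pb <- ifelse(swap, cross_parent_pairs$id_a, cross_parent_pairs$id_b)
    both <- pa %in% gA & pb %in% gB
    inA <- unique(pa[both])
    inB <- unique(pb[both])
    n_both <- sum(both)
  } else {
    inA <- inB <- character(0)
    n_both <- 0L
  }
  data.frame(metric = c(paste0(parents[1L], "_only"),
                        paste0(parents[2L], "_only"),
                        "both_retained_pairs"),
             count = c(length(setdiff(gA, inA)), length(setdiff(gB, inB)),
                       n_both),
             stringsAsFactors = FALSE)
}
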