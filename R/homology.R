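#' Per-query best hits of a hit table
#'
#' For every query id present in the table, returns its single best hit: the
#' hit with the smallest e-value, ties broken by larger percent identity,
#' then larger alignment length, then lexicographically smallest subject id.
#' Queries without hits are simply absent.
#'
#' @param hits a hit-table data.frame (see [run_backend()]).
#' @return A data.frame with one row per query id, same columns as `hits`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, hits$evalue, -hits$pident, -hits$aln_len,
             hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  out <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best bidirectional hits between two genomes
#'
#' A pair (x, y) is kept iff x's best hit in the subject genome is y and y's
#' best hit back in the query genome is x -- the operational 1:1 ortholog
#' criterion (and, within one genome, the paralog criterion). Identity and
#' e-value on the pair are taken from the forward hit.
#'
#' @param forward best hits of genome X queried against genome Y
#'   (from [best_hits()]).
#' @param reverse best hits of genome Y queried against genome X.
#' @return A data.frame of pairs with columns `id_a`, `id_b`, `genome_a`,
#'   `genome_b`, `pident`, `pgaps`, `evalue` (`a` = forward query side).
#' @export
bidirectional_best_hits <- function(forward, reverse) {
  fq <- unique(forward$query_genome)
  fs <- unique(forward$subject_genome)
  rq <- unique(reverse$query_genome)
  rs <- unique(reverse$subject_genome)
  if (nrow(forward) && nrow(reverse) &&
      (!identical(fq, rs) || !identical(fs, rq))) {
    stopf("forward (%s->%s) and reverse (%s->%s) tables are not reciprocal",
          fq, fs, rq, rs)
  }
  if (nrow(forward) == 0L || nrow(reverse) == 0L) {
    return(.empty_pairs())
  }
  rev_best <- stats::setNames(reverse$subject_id, reverse$query_id)
  keep <- !is.na(rev_best[forward$subject_id]) &
    rev_best[forward$subject_id] == forward$query_id
  f <- forward[keep, , drop = FALSE]
  pairs <- data.frame(id_a = f$query_id, id_b = f$subject_id,
                      genome_a = f$query_genome, genome_b = f$subject_genome,
                      pident = f$pident, pgaps = f$pgaps, evalue = f$evalue,
                      stringsAsFactors = FALSE)
  ## canonical storage: within one genome, order pair members lexically
  self <- pairs$genome_a == pairs$genome_b
  flip <- self & pairs$id_a > pairs$id_b
  if (any(flip)) {
    tmp <- pairs$id_a[flip]
    pairs$id_a[flip] <- pairs$id_b[flip]
    pairs$id_b[flip] <- tmp
  }
  pairs <- pairs[!duplicated(paste(pairs$id_a, pairs$id_b)), , drop = FALSE]
  pairs <- pairs[order(pairs$id_a, pairs$id_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

.empty_pairs <- function() {
  data.frame(id_a = character(0), id_b = character(0),
             genome_a = character(0), genome_b = character(0),
             pident = numeric(0), pgaps = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' 1:1 orthologs between two genomes
#'
#' Applies the identity filter and reciprocity test to a pair of hit tables
#' in opposite directions. A best hit is only considered when it shares
#' strictly more than `identity_min` percent identity with the query ORF;
#' the filter is applied to the best hits of both directions *before*
#' reciprocity testing, so a high-identity second-best hit can never be
#' promoted. Query ids whose best hit existed but failed only the identity
#' filter are reported separately (they form their own outcome category in
#' the allele classification).
#'
#' @param forward_hits hit table genome X -> genome Y.
#' @param reverse_hits hit table genome Y -> genome X.
#' @param identity_min identity threshold in percent (exclusive; default 80).
#' @param evalue_keep maximum e-value for hits entering best-hit selection.
#' @return A list with elements `pairs` (BBH pairs, see
#'   [bidirectional_best_hits()]), `subthreshold_ids` (character vector of
#'   forward-query ids whose best hit failed the identity filter) and
#'   `nonreciprocal_ids` (forward-query ids whose best hit passed the
#'   identity filter but was not reciprocated, so no allele is predicted
#'   from it).
#' @export
find_orthologs <- function(forward_hits, reverse_hits, identity_min = 80,
                           evalue_keep = 0.05) {
  if (identity_min <= 0 || identity_min >= 100) {
    stopf("'identity_min' must be in (0, 100)")
  }
  fb <- best_hits(forward_hits[forward_hits$evalue <= evalue_keep, ,
                               drop = FALSE])
  rb <- best_hits(reverse_hits[reverse_hits$evalue <= evalue_keep, ,
                               drop = FALSE])
  sub_ids <- fb$query_id[fb$pident <= identity_min]
  fb <- fb[fb$pident > identity_min, , drop = FALSE]
  rb <- rb[rb$pident > identity_min, , drop = FALSE]
  pairs <- bidirectional_best_hits(fb, rb)
  list(pairs = pairs,
       subthreshold_ids = sort(sub_ids),
       nonreciprocal_ids = sort(setdiff(fb$query_id, pairs$id_a)))
}

#' 1:1 orthologs between two parental genomes
#'
#' Same procedure as [find_orthologs()], applied between two parents rather
#' than hybrid vs parent. Used to find the parental gene pairs that share the
#' same ancestral function, e.g. for the shared-function report.
#'
#' @inheritParams find_orthologs
#' @return As [find_orthologs()].
#' @export
cross_parent_orthologs <- function(forward_hits, reverse_hits,
                                   identity_min = 80, evalue_keep = 0.05) {
  find_orthologs(forward_hits, reverse_hits, identity_min, evalue_keep)
}

#' Paralogs within one genome by self-alignment
#'
#' From a genome-vs-itself hit table, removes the trivial identity self-hits,
#' recomputes each query's best remaining hit, and keeps best bidirectional
#' hit pairs as paralogs, in canonical (lexicographic) member order.
#'
#' @param self_hits hit table whose query and subject genome are identical.
#' @param evalue_keep maximum e-value for hits entering best-hit selection.
#' @return A data.frame of paralog pairs (see [bidirectional_best_hits()]);
#'   never contains a pair (x, x).
#' @export
find_self_paralogs <- function(self_hits, evalue_keep = 0.05) {
  if (nrow(self_hits) &&
      !identical(unique(self_hits$query_genome),
                 unique(self_hits$subject_genome))) {
    stopf("find_self_paralogs() requires a genome-vs-itself hit table")
  }
  h <- self_hits[self_hits$query_id != self_hits$subject_id &
                   self_hits$evalue <= evalue_keep, , drop = FALSE]
  b <- best_hits(h)
  bidirectional_best_hits(b, b)
}

#' Merge homolog pairs into homolog groups
#'
#' Two pairs sharing a member belong to one group; transitively, groups are
#' the connected components of the graph whose edges are the pairs. Output
#' order is deterministic: groups sorted by their smallest member id, members
#' sorted within each group.
#'
#' @param pairs a data.frame of pairs with columns `id_a`, `id_b`
#'   (e.g. from [find_self_paralogs()]), or a 2-column character matrix.
#' @return A list of class `homolog_groups`: character vectors of member ids
#'   (each of size >= 2), named `grp0001`, ...; the inducing pairs are kept
#'   in attribute `evidence`.
#' @export
merge_into_groups <- function(pairs) {
  edges <- if (is.data.frame(pairs)) {
    cbind(pairs$id_a, pairs$id_b)
  } else as.matrix(pairs)
  if (is.null(edges) || nrow(edges) == 0L) {
    out <- structure(list(), class = "homolog_groups")
    attr(out, "evidence") <- pairs
    return(out)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(v) sort(unique(v)))
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  names(members) <- sprintf("grp%04d", seq_along(members))
  out <- structure(members, class = "homolog_groups")
  attr(out, "evidence") <- pairs
  out
}

#' @export
print.homolog_groups <- function(x, ...) {
  cat(sprintf("<homolog_groups> %d groups, %d members\n",
              length(x), length(unlist(x, use.names = FALSE))))
  invisible(x)
}

## flat membership table of a homolog_groups object
groups_membership <- function(groups) {
  if (length(groups) == 0L) {
    return(data.frame(group_id = character(0), member_id = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(group_id = rep(names(groups), lengths(groups)),
             member_id = unlist(groups, use.names = FALSE),
             stringsAsFactors = FALSE)
}
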