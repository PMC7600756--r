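#' Pipeline configuration
#'
#' Validated bag of options for [run_pipeline()].
#'
#' @param hybrid_fasta path to the hybrid ORF FASTA (or an [orf_set]).
#' @param parent_fastas named character vector (label = path) of 2-4 parent
#'   ORF FASTAs, or a named list of [orf_set]s.
#' @param outdir output directory (created if needed).
#' @param evalue_keep maximum e-value for saving hits.
#' @param identity_min ortholog identity threshold in percent (exclusive).
#' @param backend `"builtin"` or `"blastn"`.
#' @param propagate propagate alleles to unpredicted members of hybrid
#'   paralog pairs (final annotation step).
#' @param group_edge_layers evidence layers for hybrid homolog groups
#'   (see [hybrid_homolog_groups()]).
#' @param cross_parents also align the parents against each other to obtain
#'   cross-parent 1:1 orthologs and the shared-function (Venn) report; adds
#'   alignment jobs beyond the core 3P+1 set. Two-parent runs only.
#' @param alpha significance level used in downstream goodness-of-fit
#'   reporting.
#' @param params an [align_params] object (overrides `evalue_keep` when
#'   given).
#' @param hybrid_label genome label for the hybrid.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(hybrid_fasta, parent_fastas, outdir,
                            evalue_keep = 0.05, identity_min = 80,
                            backend = c("builtin", "blastn"),
                            propagate = TRUE,
                            group_edge_layers = c("self", "parent-paralog"),
                            cross_parents = FALSE, alpha = 0.01,
                            params = NULL, hybrid_label = "hybrid") {
  backend <- match.arg(backend)
  np <- length(parent_fastas)
  if (np < 2L || np > 4L) {
    stopf("between 2 and 4 parental genomes are supported, got %d", np)
  }
  if (is.null(names(parent_fastas)) || any(!nzchar(names(parent_fastas)))) {
    stopf("'parent_fastas' must be named by parent label")
  }
  if (identity_min <= 0 || identity_min >= 100) {
    stopf("'identity_min' must be in (0, 100)")
  }
  group_edge_layers <- match.arg(group_edge_layers,
                                 c("self", "parent-paralog",
                                   "cross-ortholog"), several.ok = TRUE)
  if (cross_parents && np != 2L) {
    stopf("'cross_parents' is only supported for 2-parent runs")
  }
  if (is.null(params)) params <- align_params(evalue_keep = evalue_keep)
  structure(list(hybrid_fasta = hybrid_fasta,
                 parent_fastas = parent_fastas, outdir = outdir,
                 evalue_keep = params$evalue_keep,
                 identity_min = identity_min, backend = backend,
                 propagate = isTRUE(propagate),
                 group_edge_layers = group_edge_layers,
                 cross_parents = isTRUE(cross_parents), alpha = alpha,
                 params = params, hybrid_label = hybrid_label),
            class = "pipeline_config")
}

.load_orfs <- function(x, label) {
  if (inherits(x, "orf_set")) return(x)
  read_orf_fasta(x, label)
}

.log_stage <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full parental-allele annotation pipeline
#'
#' Executes, in order: alignment job planning (3P+1 jobs for P parents),
#' all-vs-all alignment, best-hit extraction, 1:1 ortholog detection between
#' the hybrid and each parent, self-paralog detection in every genome,
#' parental allele assignment with the four-category classification,
#' optional allele propagation through hybrid paralog pairs, homolog group
#' construction, copy-number and summary reports. All products are TSV files
#' in `config$outdir`, listed (with md5 checksums) in `manifest.json`;
#' identical configuration and inputs give byte-identical outputs with the
#' built-in backend.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with the in-memory results (`assignments`,
#'   `summary`, `copy_numbers`, `groups`, `orthologs`, `paralogs`,
#'   `manifest`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  hyb <- .load_orfs(config$hybrid_fasta, config$hybrid_label)
  parents <- lapply(names(config$parent_fastas), function(p) {
    .load_orfs(config$parent_fastas[[p]], p)
  })
  names(parents) <- names(config$parent_fastas)
  genomes <- c(stats::setNames(list(hyb), hyb$genome_label), parents)
  .log_stage("inputs: hybrid '%s' (%d ORFs), parents %s",
             hyb$genome_label, length(hyb),
             paste(sprintf("'%s' (%d)", names(parents),
                           vapply(parents, length, integer(1))),
                   collapse = ", "))

  jobs <- plan_jobs(hyb$genome_label, names(parents))
  .log_stage("planned %d alignment jobs", nrow(jobs))

  tables <- vector("list", nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    j <- jobs[i, ]
    ti <- Sys.time()
    tables[[i]] <- run_backend(j, genomes[[j$query_genome]],
                               genomes[[j$subject_genome]],
                               config$params, config$backend)
    .log_stage("job %d/%d %s -> %s (%s): %d hits [%.1fs]", i, nrow(jobs),
               j$query_genome, j$subject_genome, j$purpose,
               nrow(tables[[i]]),
               as.numeric(difftime(Sys.time(), ti, units = "secs")))
  }
  names(tables) <- paste(jobs$query_genome, jobs$subject_genome, sep = "|")

  key <- function(a, b) paste(a, b, sep = "|")
  orthologs <- list()
  subthr <- list()
  nonrec <- list()
  for (p in names(parents)) {
    o <- find_orthologs(tables[[key(hyb$genome_label, p)]],
                        tables[[key(p, hyb$genome_label)]],
                        config$identity_min, config$evalue_keep)
    orthologs[[p]] <- o$pairs
    subthr[[p]] <- o$subthreshold_ids
    nonrec[[p]] <- o$nonreciprocal_ids
    .log_stage("orthologs hybrid~%s: %d pairs, %d subthreshold best hits",
               p, nrow(o$pairs), length(o$subthreshold_ids))
  }

  paralogs <- lapply(names(genomes), function(g) {
    find_self_paralogs(tables[[key(g, g)]], config$evalue_keep)
  })
  names(paralogs) <- names(genomes)
  for (g in names(genomes)) {
    .log_stage("paralogs in %s: %d pairs", g, nrow(paralogs[[g]]))
  }

  cross_pairs <- NULL
  if (config$cross_parents) {
    pl <- names(parents)
    jc <- list(list(query_genome = pl[1L], subject_genome = pl[2L],
                    purpose = "ortholog-forward"),
               list(query_genome = pl[2L], subject_genome = pl[1L],
                    purpose = "ortholog-reverse"))
    tf <- run_backend(jc[[1L]], parents[[1L]], parents[[2L]],
                      config$params, config$backend)
    tr <- run_backend(jc[[2L]], parents[[2L]], parents[[1L]],
                      config$params, config$backend)
    cross_pairs <- cross_parent_orthologs(tf, tr, config$identity_min,
                                          config$evalue_keep)$pairs
    .log_stage("cross-parent orthologs %s~%s: %d pairs (2 extra jobs)",
               pl[1L], pl[2L], nrow(cross_pairs))
  }

  assignments <- assign_parental_alleles(orthologs, subthr, orf_ids(hyb),
                                         config$identity_min,
                                         nonreciprocal_ids = nonrec)
  if (config$propagate) {
    assignments <- propagate_group_alleles(
      assignments, tables[[key(hyb$genome_label, hyb$genome_label)]])
  }
  .log_stage("assignment: %s",
             paste(sprintf("%s=%d", names(table(assignments$category)),
                           as.integer(table(assignments$category))),
                   collapse = ", "))

  groups <- hybrid_homolog_groups(
    paralogs[[hyb$genome_label]],
    parent_self_pairs = paralogs[names(parents)],
    cross_parent_pairs = cross_pairs, assignments = assignments,
    layers = config$group_edge_layers)
  .log_stage("hybrid homolog groups: %d", length(groups))

  summary_df <- classify_summary(assignments, groups,
                                 label = hyb$genome_label)
  cn <- copy_numbers(assignments)

  ## ---- write products -----------------------------------------------------
  out <- function(f) file.path(config$outdir, f)
  products <- character(0)
  for (p in names(parents)) {
    o <- orthologs[[p]]
    write_tsv(data.frame(hybrid_id = o$id_a, parent_id = o$id_b,
                         pident = o$pident, evalue = o$evalue),
              out(sprintf("orthologs_%s.tsv", p)))
    products <- c(products, sprintf("orthologs_%s.tsv", p))
  }
  for (g in names(genomes)) {
    write_tsv(paralogs[[g]][, c("id_a", "id_b", "pident", "evalue")],
              out(sprintf("paralogs_%s.tsv", g)))
    products <- c(products, sprintf("paralogs_%s.tsv", g))
  }
  write_tsv(assignments, out("assignments.tsv"))
  write_tsv(cn, out("copy_number.tsv"))
  gm <- groups_membership(groups)
  write_tsv(data.frame(group_id = names(groups),
                       members = vapply(groups, paste, character(1),
                                        collapse = ",")),
            out("homolog_groups.tsv"))
  write_tsv(summary_df, out("summary.tsv"))
  products <- c(products, "assignments.tsv", "copy_number.tsv",
                "homolog_groups.tsv", "summary.tsv")
  ## id mapping usable by the FASTA/GFF3 rewriters
  amap <- assignments[assignments$category == "ASSIGNED", , drop = FALSE]
  write_id_mapping(data.frame(hybrid_id = amap$hybrid_id,
                              parental_id = amap$parental_gene_id,
                              parent_label = amap$parent_label),
                   out("id_mapping.tsv"))
  products <- c(products, "id_mapping.tsv")
  venn <- NULL
  if (!is.null(cross_pairs)) {
    venn <- shared_function_report(assignments, cross_pairs)
    write_tsv(venn, out("venn_counts.tsv"))
    products <- c(products, "venn_counts.tsv")
  }

  manifest <- data.frame(
    file = products,
    md5 = unname(tools::md5sum(vapply(products, out, character(1)))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(list(products = manifest,
                            n_jobs = nrow(jobs),
                            backend = config$backend,
                            identity_min = config$identity_min,
                            evalue_keep = config$evalue_keep),
                       out("manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .log_stage("wrote %d products to %s [total %.1fs]", length(products),
             config$outdir,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(jobs = jobs, hit_tables = tables, orthologs = orthologs,
                 subthreshold_ids = subthr, paralogs = paralogs,
                 cross_parent_pairs = cross_pairs,
                 assignments = assignments, groups = groups,
                 summary = summary_df, copy_numbers = cn, venn = venn,
                 manifest = manifest,
                 group_membership = gm))
}
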