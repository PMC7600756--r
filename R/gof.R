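#' Observed vs expected parental genome content
#'
#' A content table holds, for one or more hybrid strains, the observed
#' number of ORFs assigned to each of two parents, together with the
#' fractions of the strain's gene content expected from each parent under
#' its ploidy model (e.g. 2/3 : 1/3 for an approximately triploid hybrid
#' with two chromosome sets from one parent, 1/2 : 1/2 for a balanced
#' tetraploid).
#'
#' @param observed numeric matrix of counts, one row per strain, one column
#'   per parent (row/column names recommended).
#' @param expected_fractions numeric matrix of the same shape; each row must
#'   sum to 1 (within 1e-9).
#' @return A list of class `content_table`.
#' @export
content_table <- function(observed, expected_fractions) {
  observed <- as.matrix(observed)
  expected_fractions <- as.matrix(expected_fractions)
  if (!identical(dim(observed), dim(expected_fractions))) {
    stopf("'observed' and 'expected_fractions' must have the same shape")
  }
  if (any(observed < 0)) stopf("observed counts must be >= 0")
  if (any(abs(rowSums(expected_fractions) - 1) > 1e-9)) {
    stopf("each strain's expected fractions must sum to 1")
  }
  structure(list(observed = observed,
                 expected_fractions = expected_fractions),
            class = "content_table")
}

#' Ploidy presets for expected parental fractions
#'
#' @param n_strains number of strains (rows).
#' @return A fractions matrix usable in [content_table()]:
#'   `fractions_triploid()` expects two thirds of the genes from the first
#'   parent, `fractions_balanced()` half from each.
#' @export
fractions_triploid <- function(n_strains = 1L) {
  matrix(rep(c(2 / 3, 1 / 3), each = n_strains), n_strains, 2L)
}

#' @rdname fractions_triploid
#' @export
fractions_balanced <- function(n_strains = 1L) {
  matrix(0.5, n_strains, 2L)
}

#' Chi-square goodness of fit of parental genome content
#'
#' Tests whether the observed parental allele counts of one or more hybrid
#' strains are compatible with the counts expected from their ploidy:
#' `X^2 = sum((O - E)^2 / E)` over all strain-by-parent cells, with
#' `E = strain total x expected fraction`. Degrees of freedom are
#' `cells - 1` (all cells pooled into one omnibus test, the only convention
#' consistent with a critical value of 18.48 at alpha 0.01 for 4 strains x 2
#' parents). The p-value is the upper-tail chi-square probability.
#'
#' @param table a [content_table].
#' @param alpha significance level for the reported critical value.
#' @return A list of class `gof_result` with elements `statistic`, `df`,
#'   `p_value`, `critical_value`, `alpha`, `expected`.
#' @export
chi_square_gof <- function(table, alpha = 0.01) {
  stopifnot(inherits(table, "content_table"))
  O <- table$observed
  E <- rowSums(O) * table$expected_fractions
  if (any(E <= 0)) stopf("all expected counts must be > 0")
  statistic <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = upper_tail_p(statistic, df),
                 critical_value = chi_square_critical(alpha, df),
                 alpha = alpha, expected = E),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "Chi-square goodness of fit: X^2 = %.2f, df = %d, p = %.3g\n",
    x$statistic, x$df, x$p_value))
  cat(sprintf("critical value at alpha %.3g: %.2f -> %s\n", x$alpha,
              x$critical_value,
              if (x$statistic > x$critical_value) "reject H0"
              else "do not reject H0"))
  invisible(x)
}

#' Chi-square critical value
#'
#' The (1 - alpha) quantile of the chi-square distribution with `df` degrees
#' of freedom.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return Numeric critical value.
#' @export
chi_square_critical <- function(alpha, df) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stopf("'alpha' must be in (0, 1)")
  }
  if (!is.numeric(df) || any(df < 1)) stopf("'df' must be >= 1")
  stats::qchisq(1 - alpha, df)
}

#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, evaluated without
#' underflow for extreme statistics (values down to the double-precision
#' floor near 1e-300 are returned exactly, not as 0).
#'
#' @param statistic chi-square statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return Upper-tail probability in [0, 1].
#' @export
upper_tail_p <- function(statistic, df) {
  if (!is.numeric(statistic) || any(statistic < 0)) {
    stopf("'statistic' must be >= 0")
  }
  if (!is.numeric(df) || any(df < 1)) stopf("'df' must be >= 1")
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' Read observed parental counts from a summary table
#'
#' Reconstructs the observed count matrix of a [content_table] from one or
#' more run summary files written by the pipeline (rows `assigned:<parent>`
#' of `summary.tsv`, one column per run).
#'
#' @param paths character vector of summary.tsv paths.
#' @return A counts matrix, one row per run, one column per parent.
#' @export
read_summary_counts <- function(paths) {
  rows <- lapply(paths, function(p) {
    df <- read_tsv(p)
    sel <- grepl("^assigned:", df$metric)
    stats::setNames(as.numeric(df[sel, 2L]),
                    sub("^assigned:", "", df$metric[sel]))
  })
  parents <- unique(unlist(lapply(rows, names)))
  out <- t(vapply(rows, function(r) r[parents], numeric(length(parents))))
  colnames(out) <- parents
  rownames(out) <- basename(dirname(paths))
  out
}
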