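#' Exact binomial test for up/down imbalance
#'
#' Two-sided exact binomial test with success probability 0.5 on
#' n = up + down trials, using the minimum-likelihood convention (the
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one). With no directional calls at all the test is undefined
#' and 1.0 is returned, flagged via the `"degenerate"` attribute.
#'
#' @param up,down Non-negative counts of up- and down-regulated calls.
#' @return The two-sided p-value.
#' @examples
#' binomial_imbalance(57, 61)  # ~0.78
#' binomial_imbalance(1, 3)    # 0.625
#' @export
binomial_imbalance <- function(up, down) {
  if (up < 0 || down < 0) rlang::abort("counts must be non-negative")
  n <- up + down
  if (n == 0) return(structure(1.0, degenerate = TRUE))
  stats::binom.test(up, n, p = 0.5, alternative = "two.sided")$p.value
}

#' Fisher's exact test on a 2x2 table with the sample odds ratio
#'
#' The p-value is the standard two-sided Fisher exact probability; the
#' odds ratio reported is the unconditional sample cross-product ratio
#' (a/b)/(c/d) for table [[a,b],[c,d]] — not the conditional maximum
#' likelihood estimate — so tables with a zero cell yield 0 or Inf,
#' reported as-is.
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @return A one-row tibble with `odds_ratio` and `p`.
#' @examples
#' fisher_2x2(matrix(c(1, 13, 498, 633), 2))  # OR ~0.098
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) rlang::abort("counts must be non-negative")
  if (sum(table) == 0) rlang::abort("all-zero table")
  or <- (table[1, 1] / table[1, 2]) / (table[2, 1] / table[2, 2])
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  tibble::tibble(odds_ratio = or, p = p)
}

#' Chi-square contingency test with standardized residuals
#'
#' Pearson's chi-square test of independence. Yates continuity correction
#' is applied exactly when the table is 2x2 (df = 1); larger tables use
#' the uncorrected Pearson statistic. Standardized residuals are
#' (O - E) / sqrt(E (1 - row_frac) (1 - col_frac)); cells with
#' |residual| >= 2 are conventionally read as driving the association.
#'
#' @param table An r x c matrix of non-negative counts (r, c >= 2).
#' @return A `splice_contingency` object with fields `table`, `statistic`,
#'   `df`, `p`, `odds_ratio` (2x2 only, sample cross-product, else NA),
#'   `residuals` (standardized) and `correction`.
#' @examples
#' chisq_test(matrix(c(650, 1104, 411, 662), 2))  # statistic ~0.389
#' @export
chisq_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    rlang::abort("table needs at least 2 rows and 2 columns")
  }
  if (any(table < 0)) rlang::abort("counts must be non-negative")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("expected count of zero in cell (%d, %d)",
                         bad[1], bad[2]))
  }
  correct <- all(dim(table) == 2L)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  or <- if (correct) {
    (table[1, 1] / table[1, 2]) / (table[2, 1] / table[2, 2])
  } else NA_real_
  structure(list(
    table = table,
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p = ct$p.value,
    odds_ratio = or,
    residuals = unclass(ct$stdres),
    correction = correct
  ), class = "splice_contingency")
}

#' @export
print.splice_contingency <- function(x, ...) {
  cat(sprintf("<splice_contingency> X-squared = %.4g, df = %d, p = %.3g%s\n",
              x$statistic, x$df, x$p,
              if (x$correction) " (Yates-corrected)" else ""))
  if (!is.na(x$odds_ratio)) cat(sprintf("  sample OR = %.4g\n", x$odds_ratio))
  invisible(x)
}

#' Tidy a contingency result into one row per cell
#'
#' @param x A `splice_contingency`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `observed`, `expected`,
#'   `std_residual` and `notable` (|residual| >= 2).
#' @export
tidy.splice_contingency <- function(x, ...) {
  expected <- outer(rowSums(x$table), colSums(x$table)) / sum(x$table)
  idx <- expand.grid(row = seq_len(nrow(x$table)),
                     col = seq_len(ncol(x$table)))
  tibble::tibble(
    row = idx$row, col = idx$col,
    observed = x$table[cbind(idx$row, idx$col)],
    expected = expected[cbind(idx$row, idx$col)],
    std_residual = x$residuals[cbind(idx$row, idx$col)],
    notable = abs(x$residuals[cbind(idx$row, idx$col)]) >= 2
  )
}

#' @rdname tidy.splice_contingency
#' @export
glance.splice_contingency <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p = x$p,
                 odds_ratio = x$odds_ratio, correction = x$correction)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of comparisons `m` and caps at 1.
#'
#' @param pvalues Numeric vector in [0, 1].
#' @param m Number of comparisons (>= length of `pvalues`).
#' @return Adjusted p-values.
#' @export
adjust_bonferroni <- function(pvalues, m = length(pvalues)) {
  if (length(pvalues) == 0) return(numeric(0))
  if (m <= 0) rlang::abort("m must be positive for a non-empty p-value list")
  stats::p.adjust(pvalues, method = "bonferroni", n = m)
}
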