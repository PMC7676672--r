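# The statistical procedures used throughout the analysis, as pure functions
# on counts and vectors. Chi-square, t and correlation tests delegate to
# stats::chisq.test / t.test / cor.test; Cronbach's alpha and the coefficient
# of variation are small closed forms implemented here. All p-values are
# two-sided; variances are sample (n-1) variances; no multiple-testing
# correction is applied (raw p-values are reported).

.test_result <- function(statistic, p_value, df, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = unname(df), method = method),
            class = "scub_test_result")
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction by default (counts in this analysis are in the
#' thousands); set `correct = TRUE` for the Yates-corrected 2x2 variant.
#'
#' @param table Numeric matrix of non-negative counts (R x C).
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return A `scub_test_result` with `statistic`, `p_value`,
#'   `df = (R-1)(C-1)`, `method = "chi2_contingency"`.
#' @export
chi2_contingency <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table must hold non-negative integer counts")
  }
  zr <- which(rowSums(table) == 0)
  zc <- which(colSums(table) == 0)
  if (length(zr)) stop("row ", zr[[1]], " has zero total")
  if (length(zc)) stop("column ", zc[[1]], " has zero total")
  exp_counts <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(exp_counts < 1)) stop("expected cell count below 1: table too sparse")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  .test_result(ht$statistic, ht$p.value, ht$parameter, "chi2_contingency")
}

#' Chi-square goodness-of-fit test
#'
#' @param observed Vector of non-negative counts.
#' @param expected_prop Probability vector of the same length (sums to 1).
#' @return A `scub_test_result` with `df = k - 1`,
#'   `method = "chi2_gof"`.
#' @export
chi2_gof <- function(observed, expected_prop) {
  if (length(observed) != length(expected_prop)) stop("length mismatch")
  if (abs(sum(expected_prop) - 1) > 1e-8) stop("expected proportions must sum to 1")
  ht <- suppressWarnings(stats::chisq.test(observed, p = expected_prop))
  .test_result(ht$statistic, ht$p.value, ht$parameter, "chi2_gof")
}

#' One-sample t-test against a reference value
#'
#' @param values Numeric vector, `n >= 2`, nonzero variance.
#' @param mu Reference value.
#' @return A `scub_test_result` (two-sided, `df = n - 1`,
#'   `method = "t_one_sample"`).
#' @export
t_one_sample <- function(values, mu) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::var(values) == 0) stop("zero variance: t statistic undefined")
  ht <- stats::t.test(values, mu = mu)
  .test_result(ht$statistic, ht$p.value, ht$parameter, "t_one_sample")
}

#' Two-sample t-test
#'
#' Pooled-variance (Student) test by default; `equal_var = FALSE` gives the
#' Welch variant.
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @param equal_var Assume equal variances (default `TRUE`).
#' @return A `scub_test_result` (two-sided, `method = "t_two_sample"`).
#' @export
t_two_sample <- function(a, b, equal_var = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs at least 2 values")
  ht <- stats::t.test(a, b, var.equal = equal_var)
  .test_result(ht$statistic, ht$p.value, ht$parameter, "t_two_sample")
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Numeric vectors of equal length `>= 3` with nonzero variance.
#' @return A `scub_test_result` with the correlation in `statistic_r`,
#'   the t statistic in `statistic`, and `df = n - 2`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  ht <- stats::cor.test(x, y, method = "pearson")
  out <- .test_result(ht$statistic, ht$p.value, ht$parameter, "pearson")
  out$statistic_r <- unname(ht$estimate)
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient over items measured on common cases:
#' alpha = k/(k-1) * (1 - sum of item variances / variance of case totals).
#'
#' @param items Numeric matrix, cases in rows, items in columns (`>= 2`
#'   each).
#' @return Alpha (scalar; 1 for perfectly consistent items).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2L || nrow(items) < 2L) stop("need >= 2 items and >= 2 cases")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero variance of case totals: alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean.
#'
#' @param values Numeric vector with nonzero mean.
#' @return CV (scalar).
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  stats::sd(values) / m
}
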