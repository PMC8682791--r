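# Two-group comparisons and distribution summaries following the study's
# reporting conventions (equal-variance Student's t, Mann-Whitney-Wilcoxon,
# Tukey-style boxplot summaries). No multiple-testing correction is applied:
# pairwise p-values are reported as-is.

#' Two-group comparison (Student's t or Mann-Whitney-Wilcoxon)
#'
#' `student_t` uses the classical equal-variance two-sample statistic (Welch
#' available via `var_equal = FALSE`); `mann_whitney` uses the rank-sum
#' statistic with mid-ranks for ties, exact when both groups have n <= 20 and
#' no ties occur, otherwise the normal approximation with continuity
#' correction. P-values are two-sided.
#'
#' @param a,b Numeric samples, each with n >= 2.
#' @param test `"student_t"` or `"mann_whitney"`.
#' @param var_equal For the t-test: assume equal variances (default TRUE).
#' @return One-row data frame: `test`, `n_a`, `n_b`, `statistic`, `p_value`.
#' @export
compare_groups <- function(a, b, test = c("student_t", "mann_whitney"),
                           var_equal = TRUE) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each sample needs n >= 2 (got %d and %d)", length(a), length(b))
  if (test == "student_t") {
    if (stats::var(a) + stats::var(b) == 0)
      stopf("both samples are constant; t-test undefined (zero variance)")
    ht <- stats::t.test(a, b, var.equal = var_equal)
  } else {
    exact <- length(a) <= 20L && length(b) <= 20L
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  }
  data.frame(test = test, n_a = length(a), n_b = length(b),
             statistic = unname(ht$statistic), p_value = ht$p.value,
             stringsAsFactors = FALSE)
}

#' Boxplot-style distribution summary
#'
#' Median and quartiles by linear interpolation between order statistics
#' (quantile type 7), whiskers at the most extreme data points within
#' 1.5 x IQR beyond the quartiles.
#'
#' @param sample Numeric vector, n >= 1.
#' @return One-row data frame: `median`, `q25`, `q75`, `whisker_low`,
#'   `whisker_high`, `n`.
#' @export
summarize_distribution <- function(sample) {
  x <- as.numeric(sample)
  x <- x[!is.na(x)]
  if (length(x) < 1L) stopf("empty sample")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  data.frame(median = q[2], q25 = q[1], q75 = q[3],
             whisker_low = min(x[x >= lo_fence]),
             whisker_high = max(x[x <= hi_fence]),
             n = length(x))
}
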