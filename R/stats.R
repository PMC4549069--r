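# Statistical procedures used throughout the package -----------------------

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed form
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}
#'       {1 + z^2/n}}
#' with `z` the standard normal quantile for the confidence level. The
#' Wilson interval stays well-behaved at the extreme counts that dominate
#' rare-mutation work: at `k = 0` the lower bound is exactly 0 and at
#' `k = n` the upper bound is exactly 1.
#'
#' @param k successes (vectorised).
#' @param n trials, `n >= 1`.
#' @param conf_level confidence level (default 0.95).
#' @return tibble with columns `low`, `high`.
#' @export
#' @examples
#' wilson_interval(50, 100)
wilson_interval <- function(k, n, conf_level = 0.95) {
  if (any(n < 1)) abort("wilson_interval needs n >= 1")
  if (any(k < 0 | k > n)) abort("k must lie in [0, n]")
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / denom
  tibble(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Two-sample test for equality of proportions with continuity correction
#'
#' Thin wrapper around [stats::prop.test()] (Yates-corrected chi-squared on
#' the 2x2 table, df = 1, two-sided), returned as a one-row tibble. This is
#' the test used for all frequency comparisons in the package.
#'
#' @param k1,n1 successes and trials in the first group.
#' @param k2,n2 successes and trials in the second group.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return one-row tibble: `statistic` (X-squared), `p_value`, `estimate1`,
#'   `estimate2`, `method`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = TRUE) {
  if (n1 < 1 || n2 < 1) abort("both groups need at least one trial")
  if ((k1 + k2) == 0 || (k1 + k2) == (n1 + n2)) {
    abort("degenerate 2x2 table: a marginal total is zero")
  }
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = correct)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    estimate1 = unname(ht$estimate[1]),
    estimate2 = unname(ht$estimate[2]),
    method = "2-sample test for equality of proportions with continuity correction"
  )
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Wrapper around [stats::wilcox.test()] reporting the U statistic computed
#' from midranks. Small samples without ties get the exact distribution;
#' otherwise the normal approximation with continuity correction and tie
#' correction is used (the [stats::wilcox.test()] defaults).
#'
#' @param group_a,group_b numeric vectors, both nonempty.
#' @param alternative `two.sided` (default), `less` or `greater`.
#' @return one-row tibble: `statistic` (U), `p_value`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           alternative = c("two.sided", "less", "greater")) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be nonempty")
  }
  alternative <- match.arg(alternative)
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = "Mann-Whitney U test"
  )
}

#' Correlation tests (Spearman and Pearson)
#'
#' Pearson correlation on the values, or Spearman correlation (Pearson on
#' midranks) for monotone association; both via [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param method `"spearman"` or `"pearson"`.
#' @return one-row tibble: `estimate` (r or rs), `statistic`, `p_value`,
#'   `method`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance: correlation undefined")
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble(
    estimate = unname(ht$estimate),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = paste0(method, " correlation")
  )
}
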