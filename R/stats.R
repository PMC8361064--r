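# Cohort-level statistics: Pearson correlation with Fisher-z interval and
# least-squares line, Mann-Whitney and Kruskal-Wallis group tests.

#' Pearson correlation with Fisher-z confidence interval and regression
#'
#' Returns the Pearson coefficient, its two-sided t-test p-value, a 95%
#' confidence interval from the Fisher z transform (z = atanh r, SE =
#' 1/sqrt(n-3); at n = 3 the interval is the whole of (-1, 1)), and the
#' least-squares slope and intercept of y on x.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite, each with
#'   nonzero variance.
#' @param conf_level Confidence level (default 0.95).
#' @return `list(r, ci_low, ci_high, p, n, slope, intercept)` of class
#'   `correlation_result`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("Pearson correlation needs n >= 3 pairs (got %d)", n)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stopf("values must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  # two-sided t test on n - 2 df; |r| = 1 gives p = 0
  if (abs(r) < 1) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    p <- 0
  }
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (n > 3 && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * zcrit * se)
  } else {
    ci <- c(-1, 1)
    if (abs(r) == 1) ci <- c(r, r)
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], p = p, n = n,
                 slope = slope, intercept = intercept),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, 95%% CI %.3f-%.3f, p = %.3g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n))
  cat(sprintf("least-squares fit: y = %.3g x + %.3g\n", x$slope,
              x$intercept))
  invisible(x)
}

#' Mann-Whitney two-sided test
#'
#' Two-group rank test sharing its core with [wilcoxon_rank_sum()]: exact
#' for small samples without ties, normal approximation with continuity
#' correction otherwise.
#'
#' @param x,y Numeric vectors, each with >= 2 non-missing values.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(x, y) {
  wilcoxon_rank_sum(x, y)
}

#' Kruskal-Wallis test across three or more groups
#'
#' Chi-square approximation with tie correction. With fewer than three
#' groups the call is rejected (use [mann_whitney()]). When every pooled
#' value is identical the statistic is 0 and p = 1.
#'
#' @param groups List of >= 3 numeric vectors, each with >= 2 non-missing
#'   values.
#' @return `list(statistic, df, p)`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    stopf("kruskal_wallis needs >= 3 groups; use mann_whitney for 2")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stopf("each group needs >= 2 non-missing values")
  }
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, df = length(groups) - 1, p = 1))
  }
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
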