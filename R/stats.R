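#' Paired two-tailed t-test
#'
#' Computed from the closed-form statistic `t = mean(d) / (sd(d)/sqrt(n))`
#' on the pairwise differences, with `df = n - 1`.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return a `test_result` list: `statistic`, `p_value`, `df`, `n`,
#'   `test_name`, `adjusted_p` (NA until [bonferroni()] is applied).
#' @export
paired_ttest <- function(x, y) {
  check_that(length(x) == length(y), "x and y must be paired (equal length)")
  n <- length(x)
  check_that(n >= 2L, "need at least 2 pairs", "insufficient_data")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0)) {
      # identical pairs: no evidence of a difference
      return(test_result(0, 1, "paired t-test", n, df = n - 1L))
    }
    abort_cardiact("zero variance of paired differences", "degenerate_input")
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  test_result(tstat, p, "paired t-test", n, df = n - 1L)
}

test_result <- function(statistic, p, name, n, df = NA_real_, adjusted_p = NA_real_) {
  structure(list(statistic = statistic, p_value = p, df = df,
                 test_name = name, n = n, adjusted_p = adjusted_p),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g, n = %s>\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "+")))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param m number of comparisons (>= length of `p_values`; defaults to it).
#' @return adjusted p-values `min(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  check_that(m >= 1, "m must be >= 1")
  check_that(m >= length(p_values), "m must be at least the number of p-values")
  check_that(all(p_values >= 0 & p_values <= 1), "p-values must be in [0, 1]")
  pmin(1, p_values * m)
}

# U statistic (number of (x, y) pairs with x > y, + half ties), via midranks.
mw_u_stat <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Unpaired nonparametric comparison of two samples.  For `min(n1, n2) <= 8`
#' the exact two-tailed p-value is computed by full enumeration of the
#' `choose(n1 + n2, n1)` rank assignments (midranks handle ties); otherwise
#' the normal approximation with tie-corrected variance and continuity
#' correction is used.  The two-tailed exact p is
#' `min(1, 2 min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"` (default: exact when `min(n) <= 8`), `"exact"`, or
#'   `"normal"`.
#' @return a `test_result` with `statistic` = U (for `x` relative to `y`),
#'   `n = c(n1, n2)`, and `test_name` recording the mode used.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  n1 <- length(x); n2 <- length(y)
  check_that(n1 >= 1L && n2 >= 1L, "both samples must be non-empty",
             "insufficient_data")
  if (mode == "auto") mode <- if (min(n1, n2) <= 8L) "exact" else "normal"
  u <- mw_u_stat(x, y)
  if (mode == "exact" && choose(n1 + n2, n1) > 2e6) {
    warning("exact enumeration infeasible for these sample sizes; using normal approximation")
    mode <- "normal"
  }
  if (mode == "exact") {
    pooled_ranks <- rank(c(x, y))
    offs <- n1 * (n1 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(pooled_ranks[combs], nrow = n1)) - offs
    p_le <- mean(us <= u + 1e-9)
    p_ge <- mean(us >= u - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    return(test_result(u, p, "Mann-Whitney U (exact)", c(n1, n2)))
  }
  n <- n1 + n2
  ties <- table(c(x, y))
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  check_that(sigma2 > 0, "all observations tied; U variance is zero",
             "degenerate_input")
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  test_result(u, min(1, p), "Mann-Whitney U (normal approx.)", c(n1, n2))
}

#' Pearson correlation with two-tailed p
#'
#' `r` from the product-moment formula; p from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` with `df = n - 2` (p = 0 at |r| = 1).
#'
#' @param x,y numeric vectors, equal length, n >= 3, non-constant.
#' @return a `correlation_result` list: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  check_that(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  check_that(n >= 3L, "need n >= 3", "insufficient_data")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    abort_cardiact("zero variance: correlation undefined", "degenerate_input")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<pearson: r = %.4f, p = %.4g, n = %d>\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' Normality gate (Shapiro-Wilk)
#'
#' Routes downstream comparisons: a failed gate (p < alpha) indicates the
#' nonparametric Mann-Whitney test should be used instead of a t-test.
#' A constant sample is degenerate and reported as a flagged failure.
#'
#' @param x numeric vector, n >= 3.
#' @param alpha significance level of the gate (default 0.05).
#' @return list: `pass`, `p_value`, `degenerate`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  check_that(length(x) >= 3L, "need n >= 3", "insufficient_data")
  if (stats::sd(x) == 0)
    return(list(pass = FALSE, p_value = NA_real_, degenerate = TRUE))
  # shapiro.test caps n at 5000; subsample deterministically above that
  xx <- if (length(x) > 5000L) x[seq(1L, length(x), length.out = 5000L)] else x
  p <- stats::shapiro.test(xx)$p.value
  list(pass = p >= alpha, p_value = p, degenerate = FALSE)
}
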