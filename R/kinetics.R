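#' Cumulative trapezoidal integral of a curve
#'
#' The Patlak numerator: integral of the curve from time zero.  If the curve
#' starts after t = 0, the value at t = 0 is taken as 0 and the first
#' trapezoid spans the gap.
#'
#' @param curve a [tracer_curve()].
#' @return a [tracer_curve()] of the running integral on the input grid.
#' @export
cumulative_integral <- function(curve) {
  check_that(nrow(curve) >= 1L, "curve is empty", "format_error")
  t <- curve$time_min; v <- curve$value
  if (t[1L] > 0) { t <- c(0, t); v <- c(0, v) }
  ci <- c(0, cumsum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2))
  keep <- match(curve$time_min, t)
  tracer_curve(curve$time_min, ci[keep],
               paste0("int_", curve_label(curve)))
}

#' Patlak transform of a tissue/plasma curve pair
#'
#' Computes the Patlak coordinates `x = int_0^t Cp dtau / Cp(t)` (normalized
#' integrated plasma exposure, min) and `y = Ct(t)/Cp(t)`.  If the plasma
#' grid differs from the tissue grid, plasma is linearly interpolated onto
#' the tissue grid (tissue frames set the native resolution).  Samples with
#' `Cp` below `eps_frac` of the plasma maximum are dropped and counted.
#'
#' @param tissue tissue [tracer_curve()].
#' @param plasma plasma [tracer_curve()].
#' @param eps_frac relative plasma floor (default 1e-9).
#' @return a `patlak_points` data.frame with columns `t`, `x`, `y` and an
#'   `n_dropped` attribute.
#' @export
patlak_points <- function(tissue, plasma, eps_frac = 1e-9) {
  check_that(nrow(tissue) >= 1L && nrow(plasma) >= 1L,
             "empty input curve", "insufficient_data")
  if (!isTRUE(all.equal(tissue$time_min, plasma$time_min)))
    plasma <- interp_curve(plasma, tissue$time_min)
  intcp <- cumulative_integral(plasma)$value
  cp <- plasma$value
  keep <- cp > eps_frac * max(cp)
  if (sum(keep) < 3L)
    abort_cardiact("fewer than 3 usable Patlak samples (plasma near zero)",
                   "insufficient_data")
  structure(data.frame(t = tissue$time_min[keep],
                       x = intcp[keep] / cp[keep],
                       y = tissue$value[keep] / cp[keep]),
            n_dropped = sum(!keep),
            class = c("patlak_points", "data.frame"))
}

#' Fit a Patlak line in a protocol window
#'
#' Ordinary least-squares line through the Patlak points whose time lies in
#' the closed window; the slope is the net influx constant Ki (1/min) and
#' the intercept the apparent distribution volume.
#'
#' @param points a [patlak_points()] object.
#' @param window `c(start, end)` in minutes; boundary points are included.
#' @return a `patlak_fit` list: `ki`, `intercept`, `r2`, `window`, `n_points`.
#' @export
fit_patlak <- function(points, window) {
  check_that(length(window) == 2L && window[2L] > window[1L],
             "window must be [start, end] with end > start")
  sel <- points$t >= window[1L] & points$t <= window[2L]
  if (sum(sel) < 3L)
    abort_cardiact(sprintf("fewer than 3 Patlak points in window [%g, %g] min",
                           window[1L], window[2L]), "insufficient_data")
  x <- points$x[sel]; y <- points$y[sel]
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  check_that(sxx > 0, "degenerate window: all x identical", "degenerate_input")
  sxy <- sum((x - mx) * (y - my))
  ki <- sxy / sxx
  intercept <- my - ki * mx
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
  structure(list(ki = ki, intercept = intercept, r2 = r2,
                 window = as.numeric(window), n_points = sum(sel)),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit [%g, %g] min: Ki = %.5g /min, intercept = %.4g, r2 = %.4f, n = %d>\n",
              x$window[1L], x$window[2L], x$ki, x$intercept, x$r2, x$n_points))
  invisible(x)
}

#' Metabolic rate of glucose from a Patlak slope
#'
#' `MRGlu = Ki * blood glucose / LC` using the blood glucose measured at the
#' start of the study.  The lumped constant defaults to 1 so MRGlu is in
#' (glucose units)/min; only relative comparisons are drawn from it.
#'
#' @param ki Patlak influx constant, 1/min.
#' @param glucose blood glucose concentration (>= 0).
#' @param lc lumped constant (> 0, default 1).
#' @return an `mrglu_result` list: `mrglu`, `ki`, `glucose`, `lc`.
#' @export
mrglu <- function(ki, glucose, lc = 1.0) {
  check_that(lc > 0, "lumped constant must be > 0")
  check_that(glucose >= 0, "glucose must be >= 0")
  structure(list(mrglu = ki * glucose / lc, ki = ki, glucose = glucose, lc = lc),
            class = "mrglu_result")
}

#' Percent decrease between two values
#'
#' `100 (before - after) / before`, truncated toward zero to an integer by
#' default — the convention under which mean MRGlu 0.109 -> 0.027 prints as a
#' 75% decrease and 0.083 -> 0.007 as 91%.
#'
#' @param before baseline value (> 0).
#' @param after later value.
#' @param rounding `"truncate"` (default) or `"none"`.
#' @return percent change (integer-valued when truncated).
#' @export
percent_change <- function(before, after, rounding = c("truncate", "none")) {
  rounding <- match.arg(rounding)
  check_that(before > 0, "before must be > 0")
  pc <- 100 * (before - after) / before
  # tiny epsilon so exact-decimal cases (e.g. a -> 0.9 a giving
  # 9.999999999999995) truncate to the intended integer
  if (rounding == "truncate") sign(pc) * floor(abs(pc) + 1e-9) else pc
}

#' Percent reduction in apparent obstructed-core volume
#'
#' @param v_early volume at the early measurement (cm^3 or voxels), > 0.
#' @param v_late volume at the late measurement, >= 0.
#' @return `100 (v_early - v_late) / v_early` (not rounded).
#' @export
volume_reduction <- function(v_early, v_late) {
  check_that(v_early > 0, "v_early must be > 0")
  check_that(v_late >= 0, "v_late must be >= 0")
  100 * (v_early - v_late) / v_early
}
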