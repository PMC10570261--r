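#' Tracer concentration curve
#'
#' A sampled time series (minutes from infusion start vs concentration) for a
#' plasma/blood input function or a tissue region, FDG or Gd.
#'
#' @param times numeric, minutes, strictly increasing.
#' @param values numeric concentrations (activity/mL for FDG, mM for Gd),
#'   finite, same length as `times`.
#' @param label short text label (e.g. `"plasma_fdg"`, `"inot"`).
#' @return An object of class `tracer_curve`: a data.frame with columns
#'   `time_min`, `value` and a `label` attribute.
#' @export
tracer_curve <- function(times, values, label = "curve") {
  check_that(length(times) == length(values),
             "times and values must have equal length", "format_error")
  check_that(length(times) >= 1L, "curve must be non-empty", "format_error")
  check_that(all(is.finite(times)) && all(is.finite(values)),
             "curve samples must be finite", "format_error")
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    abort_cardiact(sprintf("times must be strictly increasing (sample %d)", bad),
                   "format_error")
  }
  structure(data.frame(time_min = as.numeric(times), value = as.numeric(values)),
            label = as.character(label)[1L],
            class = c("tracer_curve", "data.frame"))
}

curve_label <- function(curve) attr(curve, "label") %||% "curve"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tracer_curve <- function(x, ...) {
  cat(sprintf("<tracer_curve '%s': %d samples, t = %.6g..%.6g min>\n",
              curve_label(x), nrow(x), x$time_min[1L], x$time_min[nrow(x)]))
  invisible(x)
}

# Linear interpolation of a curve onto new times (no extrapolation).
interp_curve <- function(curve, times, label = curve_label(curve)) {
  rng <- range(curve$time_min)
  check_that(all(times >= rng[1L] - 1e-9) && all(times <= rng[2L] + 1e-9),
             "requested times fall outside the curve range", "range_error")
  v <- stats::approx(curve$time_min, curve$value, xout = pmin(pmax(times, rng[1L]), rng[2L]),
                     rule = 1)$y
  tracer_curve(times, v, label)
}

#' Average a fine curve into contiguous frames
#'
#' Emulates PET framing: the fine-grid curve is averaged over consecutive
#' frames of `frame_min` minutes and reported at the frame midpoints.
#'
#' @param curve a [tracer_curve()].
#' @param frame_min frame duration in minutes (default 3, the protocol's
#'   reconstruction framing).
#' @return a [tracer_curve()] at frame midpoints.
#' @export
frame_curve <- function(curve, frame_min = 3) {
  check_that(is.numeric(frame_min) && frame_min > 0, "frame_min must be > 0")
  t0 <- curve$time_min[1L]
  t1 <- curve$time_min[nrow(curve)]
  starts <- seq(t0, t1 - frame_min + 1e-9, by = frame_min)
  check_that(length(starts) >= 1L, "curve shorter than one frame", "insufficient_data")
  mids <- starts + frame_min / 2
  vals <- vapply(starts, function(s) {
    sel <- curve$time_min >= s - 1e-9 & curve$time_min <= s + frame_min + 1e-9
    mean(curve$value[sel])
  }, numeric(1))
  tracer_curve(mids, vals, curve_label(curve))
}

#' Multiplicative Gaussian noise on a curve
#'
#' Each sample is multiplied by `1 + cv * N(0, 1)`, the ROI-level noise model
#' used for reconstructed time-activity frames.
#'
#' @param curve a [tracer_curve()].
#' @param cv coefficient of variation (e.g. 0.05 for 5% noise).
#' @param seed optional integer seed for reproducibility.
#' @return a noisy [tracer_curve()]; values are floored at 0.
#' @export
add_tac_noise <- function(curve, cv, seed = NULL) {
  check_that(is.numeric(cv) && cv >= 0, "cv must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- curve$value * (1 + cv * stats::rnorm(nrow(curve)))
  tracer_curve(curve$time_min, pmax(v, 0), curve_label(curve))
}
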