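#' Extracellular volume from T1 of myocardium and blood
#'
#' `ECV = (1 - hct) * (1/post_myo - 1/native_myo) / (1/post_blood -
#' 1/native_blood)`.  The ratio of R1 changes is unit-scale invariant, so T1
#' may be given in ms or s as long as all four values agree.  Estimates
#' outside `[0, 1]` are flagged (with a warning), not clamped or errored:
#' noise can push ECV outside the physical range and silent clamping would
#' hide it.
#'
#' @param native_t1_myo,post_t1_myo native and post-contrast myocardial T1.
#' @param native_t1_blood,post_t1_blood native and post-contrast blood T1.
#' @param hct hematocrit fraction (default 0.45, the protocol's assumption).
#' @param timepoint optional timepoint label, minutes.
#' @return an `ecv_result` list: `ecv`, `timepoint`, `flagged`, `inputs`.
#' @export
compute_ecv <- function(native_t1_myo, post_t1_myo,
                        native_t1_blood, post_t1_blood,
                        hct = 0.45, timepoint = NA_real_) {
  check_that(all(c(native_t1_myo, post_t1_myo, native_t1_blood, post_t1_blood) > 0),
             "all T1 values must be > 0")
  check_that(hct > 0 && hct < 1, "hct must be in (0, 1)")
  dr1_blood <- 1 / post_t1_blood - 1 / native_t1_blood
  if (abs(dr1_blood) < .Machine$double.eps * 100 / native_t1_blood)
    abort_cardiact("blood R1 change is zero: no contrast arrived in blood",
                   "degenerate_input")
  dr1_myo <- 1 / post_t1_myo - 1 / native_t1_myo
  ecv <- (1 - hct) * dr1_myo / dr1_blood
  flagged <- ecv < 0 || ecv > 1
  if (flagged)
    warning(sprintf("ECV estimate %.4g outside [0, 1]; flagged", ecv))
  structure(list(ecv = ecv, timepoint = timepoint, flagged = flagged,
                 inputs = list(native_t1_myo = native_t1_myo,
                               post_t1_myo = post_t1_myo,
                               native_t1_blood = native_t1_blood,
                               post_t1_blood = post_t1_blood, hct = hct)),
            class = "ecv_result")
}

#' @export
print.ecv_result <- function(x, ...) {
  cat(sprintf("<ecv_result%s: ECV = %.4f%s>\n",
              if (is.na(x$timepoint)) "" else sprintf(" @%g min", x$timepoint),
              x$ecv, if (x$flagged) " [FLAGGED outside 0-1]" else ""))
  invisible(x)
}

#' ECV at the protocol timepoints from a sampled T1 table
#'
#' For each requested timepoint the nearest table row within `tol` minutes is
#' used as the post-contrast T1 pair; shared native values supply the
#' pre-contrast T1.  The default tolerance of 5 min is half the 10-min T1
#' sampling interval.
#'
#' @param t1_table a `t1_table` (see [sample_molli()]) with columns
#'   `time_min`, `t1_myo_ms`, `t1_blood_ms`.
#' @param native_t1_myo,native_t1_blood native (pre-contrast) T1, ms.
#' @param timepoints minutes (default `c(40, 90, 150)`).
#' @param hct hematocrit fraction.
#' @param tol nearest-sample tolerance, minutes.
#' @return list of `ecv_result`, one per timepoint.
#' @export
ecv_timeseries <- function(t1_table, native_t1_myo, native_t1_blood,
                           timepoints = c(40, 90, 150), hct = 0.45, tol = 5) {
  check_that(all(c("time_min", "t1_myo_ms", "t1_blood_ms") %in% names(t1_table)),
             "t1_table must have columns time_min, t1_myo_ms, t1_blood_ms",
             "format_error")
  lapply(timepoints, function(tp) {
    d <- abs(t1_table$time_min - tp)
    i <- which.min(d)
    if (d[i] > tol)
      abort_cardiact(sprintf("no T1 sample within %g min of t = %g min", tol, tp),
                     "insufficient_data")
    compute_ecv(native_t1_myo, t1_table$t1_myo_ms[i],
                native_t1_blood, t1_table$t1_blood_ms[i],
                hct = hct, timepoint = tp)
  })
}
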