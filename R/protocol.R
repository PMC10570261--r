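#' Constant-infusion protocol description
#'
#' Describes the 150-min simultaneous constant infusion of Gd-DTPA and FDG
#' with glucose suppression (heparin bolus + lipid infusion) starting at
#' 40 min, and the three analysis windows identified as "before", "during"
#' and "after" suppression.
#'
#' @param t_start,t_end infusion start/end, minutes (defaults 0 and 150).
#' @param gd_rate Gd-DTPA infusion rate, umol/min/kg (default 4).
#' @param fdg_rate FDG infusion rate, MBq/min/kg. The study administered a
#'   total of 25 MBq/kg over the infusion; the rate is exposed as a free
#'   parameter (default 25/150).
#' @param suppression_onset minute at which heparin is given and the lipid
#'   infusion starts (default 40).
#' @param lipid_duration lipid infusion duration, minutes (default 50).
#' @param windows list of three `c(start, end)` intervals in minutes
#'   (defaults 10-40, 60-90, 120-150).
#' @return an object of class `infusion_protocol`.
#' @export
infusion_protocol <- function(t_start = 0, t_end = 150,
                              gd_rate = 4, fdg_rate = 25 / 150,
                              suppression_onset = 40, lipid_duration = 50,
                              windows = list(c(10, 40), c(60, 90), c(120, 150))) {
  check_that(t_end > t_start, "t_end must exceed t_start")
  check_that(gd_rate >= 0 && fdg_rate >= 0, "infusion rates must be >= 0")
  check_that(is.list(windows) && length(windows) == 3L &&
               all(vapply(windows, length, 1L) == 2L),
             "windows must be three [start, end] intervals")
  w <- do.call(rbind, lapply(windows, as.numeric))
  check_that(all(w[, 2] > w[, 1]), "each window must have end > start")
  check_that(all(w >= t_start) && all(w <= t_end),
             "windows must lie inside [t_start, t_end]")
  check_that(all(diff(as.vector(t(w))) > 0), "windows must be disjoint and ordered")
  check_that(suppression_onset < w[2, 1],
             "suppression_onset must precede the 'during' window")
  structure(list(t_start = t_start, t_end = t_end,
                 gd_rate = gd_rate, fdg_rate = fdg_rate,
                 suppression_onset = suppression_onset,
                 lipid_duration = lipid_duration,
                 windows = lapply(seq_len(3), function(i) w[i, ])),
            class = "infusion_protocol")
}

#' @export
print.infusion_protocol <- function(x, ...) {
  cat(sprintf("<infusion_protocol: %g-%g min, Gd %g umol/min/kg, FDG %g MBq/min/kg>\n",
              x$t_start, x$t_end, x$gd_rate, x$fdg_rate))
  cat(sprintf("  suppression at %g min; windows %s\n", x$suppression_onset,
              paste(vapply(x$windows, function(w) sprintf("[%g,%g]", w[1], w[2]),
                           character(1)), collapse = " ")))
  invisible(x)
}

#' Total administered Gd-DTPA dose
#'
#' Rate times infusion duration, converted from umol/kg to mmol/kg
#' (4 umol/min/kg over 150 min gives 0.6 mmol/kg).
#'
#' @param protocol an [infusion_protocol()].
#' @return total dose in mmol/kg.
#' @export
total_gd_dose <- function(protocol) {
  check_that(inherits(protocol, "infusion_protocol"),
             "protocol must be an infusion_protocol")
  protocol$gd_rate * (protocol$t_end - protocol$t_start) / 1000
}

#' Names of the three analysis windows
#' @keywords internal
window_names <- function() c("before", "during", "after")
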