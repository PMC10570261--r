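#' Upper bound on the viable-myocyte volume fraction
#'
#' Tissue-fraction ledger: whatever volume is not extracellular space,
#' collagen or fibroblasts is the most that viable myocytes can occupy, so
#' the bound is `1 - ecv - fibrosis - fibroblast`.  With the day-5
#' post-infarction estimates (ECV 0.48, fibrosis 0.04, fibroblasts 0.04) the
#' bound is 0.44.
#'
#' @param ecv extracellular volume fraction.
#' @param fibrosis collagen volume fraction.
#' @param fibroblast fibroblast volume fraction.
#' @return the viable-myocyte fraction bound in `[0, 1]`.
#' @export
viable_myocyte_bound <- function(ecv, fibrosis, fibroblast) {
  check_that(all(c(ecv, fibrosis, fibroblast) >= 0) &&
               all(c(ecv, fibrosis, fibroblast) <= 1),
             "fractions must be in [0, 1]")
  s <- ecv + fibrosis + fibroblast
  if (s > 1)
    abort_cardiact(sprintf("ledger infeasible: fractions sum to %.4g > 1", s),
                   "infeasible_budget")
  1 - s
}

#' Fraction of the healthy-myocardium baseline
#'
#' Ratio of a tissue fraction to the baseline myocyte occupancy of normal
#' left-ventricular myocardium (~0.75).
#'
#' @param numerator a volume fraction.
#' @param baseline baseline myocyte fraction (> 0, default 0.75).
#' @return `numerator / baseline`.
#' @export
fraction_of_baseline <- function(numerator, baseline = 0.75) {
  check_that(baseline > 0, "baseline must be > 0")
  numerator / baseline
}

#' Viable fraction needed to explain the infarct-zone suppression response
#'
#' Interprets "what fraction of infarct-zone cells would have to be normal
#' myocytes for the infarct's metabolic drop to be purely myocyte
#' suppression" as the ratio of fractional decreases:
#' `[(infarct_before - infarct_after)/infarct_before] /
#'  [(remote_before - remote_after)/remote_before]`.
#' This is an interpretation (flagged in the result), not a stated formula.
#'
#' @param infarct_before,infarct_after infarct-zone MRGlu means (`before > 0`).
#' @param remote_before,remote_after remote-tissue MRGlu means (`before > 0`).
#' @return list: `fraction`, `interpretation = TRUE`.
#' @export
required_viable_fraction <- function(infarct_before, infarct_after,
                                     remote_before, remote_after) {
  check_that(infarct_before > 0 && remote_before > 0,
             "baseline (before) values must be > 0")
  remote_drop <- (remote_before - remote_after) / remote_before
  if (remote_drop <= 0)
    abort_cardiact("remote tissue shows no decrease; ratio undefined",
                   "undefined_ratio")
  infarct_drop <- (infarct_before - infarct_after) / infarct_before
  list(fraction = infarct_drop / remote_drop, interpretation = TRUE)
}

#' Assemble a complete volume budget
#'
#' @param ecv,fibrosis,fibroblast fractions (see [viable_myocyte_bound()]).
#' @param baseline_myocyte baseline myocyte fraction (default 0.75).
#' @return a `volume_budget` list whose four components sum to 1:
#'   `ecv`, `fibrosis`, `fibroblast`, `myocyte_bound`, plus
#'   `baseline_myocyte` and `fraction_of_baseline` (bound / baseline).
#' @export
volume_budget <- function(ecv, fibrosis, fibroblast, baseline_myocyte = 0.75) {
  bound <- viable_myocyte_bound(ecv, fibrosis, fibroblast)
  structure(list(ecv = ecv, fibrosis = fibrosis, fibroblast = fibroblast,
                 myocyte_bound = bound, baseline_myocyte = baseline_myocyte,
                 fraction_of_baseline = fraction_of_baseline(bound, baseline_myocyte)),
            class = "volume_budget")
}

#' @export
print.volume_budget <- function(x, ...) {
  cat(sprintf("<volume_budget: ECV %.2f + fibrosis %.2f + fibroblast %.2f -> myocytes <= %.2f (%.0f%% of baseline %.2f)>\n",
              x$ecv, x$fibrosis, x$fibroblast, x$myocyte_bound,
              100 * x$fraction_of_baseline, x$baseline_myocyte))
  invisible(x)
}
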