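#' Simulate slow Gd penetration of an obstructed infarct core
#'
#' Each voxel of the obstructed region is assigned a very low `ktrans` drawn
#' uniformly from `ktrans_range`; its tissue Gd concentration is propagated
#' with the exact exchange update of [simulate_tissue_gd()].  A voxel still
#' *appears* obstructed at time t while its tissue concentration is below
#' `detection_fraction` times the fully-mixed reference concentration
#' `ve Cp(t) + vp Cb(t)` of equilibrated infarcted tissue.  As the constant
#' infusion proceeds, voxels fill and the apparent obstructed volume shrinks.
#'
#' @param n_voxels number of voxels in the obstructed core (> 0).
#' @param ktrans_range `c(lo, hi)` range of low exchange constants, 1/min.
#' @param detection_fraction detectability threshold in (0, 1).
#' @param times measurement times, minutes (default `c(30, 150)`).
#' @param plasma_gd plasma Gd [tracer_curve()].
#' @param kin a [gd_kinetics()] object (supplies ve, vp, hct).
#' @param seed optional integer seed.
#' @return named numeric vector: apparent obstructed volume (voxel count) at
#'   each requested time.
#' @export
simulate_iot_grid <- function(n_voxels, ktrans_range = c(0, 0.01),
                              detection_fraction = 0.5, times = c(30, 150),
                              plasma_gd, kin = gd_kinetics(ve = 0.48, vp = 0.02),
                              seed = NULL) {
  check_that(is.numeric(n_voxels) && n_voxels >= 1, "empty voxel grid")
  check_that(detection_fraction > 0 && detection_fraction < 1,
             "detection_fraction must be in (0, 1)")
  check_that(all(ktrans_range >= 0) && length(ktrans_range) == 2L,
             "ktrans_range must be two non-negative values")
  rng <- range(plasma_gd$time_min)
  check_that(all(times >= rng[1L] & times <= rng[2L]),
             "measurement times outside plasma range", "range_error")
  if (!is.null(seed)) set.seed(as.integer(seed))
  kt <- stats::runif(n_voxels, ktrans_range[1L], ktrans_range[2L])
  a <- ifelse(kt > 0, kt / kin$ve, 0)
  ce <- gd_interstitial(plasma_gd$time_min, plasma_gd$value, a)
  if (is.null(dim(ce))) ce <- matrix(ce, ncol = 1L)
  cb <- (1 - kin$hct) * plasma_gd$value
  idx <- vapply(times, function(t) which.min(abs(plasma_gd$time_min - t)), 1L)
  out <- vapply(idx, function(i) {
    tissue <- kin$ve * ce[i, ] + kin$vp * cb[i]
    ref <- kin$ve * plasma_gd$value[i] + kin$vp * cb[i]
    sum(tissue < detection_fraction * ref)
  }, numeric(1))
  stats::setNames(out, paste0("t", times))
}
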