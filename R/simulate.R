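#' FDG two-tissue irreversible kinetic parameters
#'
#' Micro-parameters of the irreversible two-tissue compartment model used by
#' the simulator.  Glucose suppression is modelled as a smooth (logistic)
#' reduction of the trapping rate `k3` to `suppression_factor * k3` around
#' the suppression onset; the macro-parameter recovered by Patlak analysis is
#' `Ki = K1 * k3 / (k2 + k3)`.
#'
#' @param K1 plasma-to-tissue transfer, mL/min/mL.
#' @param k2 tissue-to-plasma rate, 1/min.
#' @param k3 trapping (phosphorylation) rate, 1/min.
#' @param vb fractional blood volume in the ROI, 0 <= vb < 1.
#' @param suppression_factor multiplier applied to `k3` after onset,
#'   0 < factor <= 1 (1 = no suppression).
#' @param transition_tau logistic time constant of the suppression onset,
#'   minutes (default 5; reproduces a visible effect ~20 min after onset).
#' @return an object of class `fdg_kinetics`.
#' @export
fdg_kinetics <- function(K1 = 0.1, k2 = 0.15, k3 = 0.05, vb = 0.1,
                         suppression_factor = 1, transition_tau = 5) {
  check_that(K1 >= 0 && k2 >= 0 && k3 >= 0, "rate constants must be >= 0")
  check_that(vb >= 0 && vb < 1, "vb must be in [0, 1)")
  check_that(suppression_factor > 0 && suppression_factor <= 1,
             "suppression_factor must be in (0, 1]")
  check_that(transition_tau > 0, "transition_tau must be > 0")
  structure(list(K1 = K1, k2 = k2, k3 = k3, vb = vb,
                 suppression_factor = suppression_factor,
                 transition_tau = transition_tau),
            class = "fdg_kinetics")
}

#' Analytic Patlak influx constant of a parameter set
#' @param kin an [fdg_kinetics()] object.
#' @param suppressed if TRUE, use the late (suppressed) k3.
#' @return Ki = K1 k3 / (k2 + k3), 1/min (0 when all rates are 0).
#' @export
analytic_ki <- function(kin, suppressed = FALSE) {
  k3 <- kin$k3 * if (suppressed) kin$suppression_factor else 1
  if (kin$k2 + k3 == 0) return(0)
  kin$K1 * k3 / (kin$k2 + k3)
}

#' Gd-DTPA exchange and relaxometry parameters
#'
#' Tofts-type two-site exchange (plasma <-> interstitium) plus the linear
#' relaxivity model converting tissue/blood Gd concentration to T1.  Gd-DTPA
#' is confined to plasma, so whole-blood concentration is
#' `(1 - hct) * plasma concentration`.
#'
#' @param ktrans volume transfer constant, 1/min.
#' @param ve interstitial (extravascular extracellular) volume fraction.
#' @param vp plasma volume fraction; `ve + vp <= 1`.
#' @param r1 longitudinal relaxivity, 1/(mM s) (default 4.5 at 3 T).
#' @param t10_tissue,t10_blood native T1 values, ms (defaults 1100, 1600).
#' @param hct hematocrit fraction (default 0.45, the protocol's assumed value).
#' @return an object of class `gd_kinetics`.
#' @export
gd_kinetics <- function(ktrans = 0.2, ve = 0.2, vp = 0.05, r1 = 4.5,
                        t10_tissue = 1100, t10_blood = 1600, hct = 0.45) {
  check_that(ktrans >= 0, "ktrans must be >= 0")
  check_that(ve >= 0 && vp >= 0 && ve + vp <= 1, "need 0 <= ve + vp <= 1")
  check_that(r1 > 0, "r1 must be > 0")
  check_that(t10_tissue > 0 && t10_blood > 0, "native T1 values must be > 0")
  check_that(hct > 0 && hct < 1, "hct must be in (0, 1)")
  if (ktrans > 0 && ve == 0)
    abort_cardiact("ve = 0 with ktrans > 0 is degenerate", "invalid_parameter")
  structure(list(ktrans = ktrans, ve = ve, vp = vp, r1 = r1,
                 t10_tissue = t10_tissue, t10_blood = t10_blood, hct = hct),
            class = "gd_kinetics")
}

#' Simulate a constant-infusion plasma curve
#'
#' One-compartment plasma model under constant infusion: `dCp/dt = rate/vd -
#' kel * Cp`, i.e. `Cp(t) = rate/(vd kel) (1 - exp(-kel t))`, the linear ramp
#' `rate t / vd` in the `kel = 0` limit.  Concentrations are decay-corrected
#' (the scanner applied automatic decay correction), so no decay term appears.
#'
#' @param protocol an [infusion_protocol()].
#' @param rate infusion rate per kg (defaults to the protocol's Gd rate).
#' @param vd apparent distribution volume, mL/kg.
#' @param kel elimination rate, 1/min (>= 0).
#' @param grid time step of the output grid, minutes.
#' @param noise_cv multiplicative noise CV applied when `seed` is given.
#' @param seed optional integer seed.
#' @param label curve label.
#' @return a [tracer_curve()] sampled on `seq(t_start, t_end, grid)`.
#' @export
simulate_plasma_curve <- function(protocol, rate = protocol$gd_rate,
                                  vd = 200, kel = 0.02, grid = 0.5,
                                  noise_cv = 0, seed = NULL, label = "plasma") {
  check_that(inherits(protocol, "infusion_protocol"),
             "protocol must be an infusion_protocol")
  check_that(vd > 0, "vd must be > 0")
  check_that(kel >= 0, "kel must be >= 0")
  check_that(grid > 0, "grid must be > 0")
  times <- seq(protocol$t_start, protocol$t_end, by = grid)
  rel <- times - protocol$t_start
  cp <- if (kel == 0) rate * rel / vd else rate / (vd * kel) * (1 - exp(-kel * rel))
  out <- tracer_curve(times, cp, label)
  if (!is.null(seed) && noise_cv > 0) out <- add_tac_noise(out, noise_cv, seed)
  out
}

# logistic trapping-rate schedule: k3 -> suppression_factor * k3 around onset
k3_schedule <- function(kin, t, onset) {
  kin$k3 * (1 - (1 - kin$suppression_factor) *
              stats::plogis((t - onset) / kin$transition_tau))
}

#' Simulate an FDG tissue curve with mid-infusion suppression
#'
#' Integrates the irreversible two-tissue model
#' `dC1/dt = K1 Cp - (k2 + k3(t)) C1`, `dC2/dt = k3(t) C1`, with the
#' time-varying trapping rate of [fdg_kinetics()], by classical RK4 on a
#' refined grid (plasma linearly interpolated).  The measured ROI value is
#' `Ct = C1 + C2 + vb * Cp`.
#'
#' @param plasma a plasma [tracer_curve()].
#' @param kin an [fdg_kinetics()] object.
#' @param onset suppression onset, minutes; must lie within the plasma range.
#' @param dt integration substep, minutes (default 0.05).
#' @param label curve label.
#' @return a [tracer_curve()] on the plasma time grid.
#' @export
simulate_tissue_fdg <- function(plasma, kin, onset = 40, dt = 0.05,
                                label = "tissue_fdg") {
  check_that(inherits(kin, "fdg_kinetics"), "kin must be fdg_kinetics")
  check_that(nrow(plasma) >= 2L, "plasma curve too short", "insufficient_data")
  rng <- range(plasma$time_min)
  check_that(onset >= rng[1L] && onset <= rng[2L],
             "onset must lie within the plasma time range", "range_error")
  cp_fun <- stats::approxfun(plasma$time_min, plasma$value, rule = 2)
  k3_fun <- function(t) k3_schedule(kin, t, onset)
  deriv <- function(t, y) {
    k3t <- k3_fun(t)
    cp <- cp_fun(t)
    c(kin$K1 * cp - (kin$k2 + k3t) * y[1L], k3t * y[1L])
  }
  sol <- rk4_solve(deriv, y0 = c(0, 0), times = plasma$time_min, dt = dt)
  ct <- sol[, 1L] + sol[, 2L] + kin$vb * plasma$value
  tracer_curve(plasma$time_min, ct, label)
}

# Fixed-step RK4 over the output times, each interval split into substeps <= dt.
rk4_solve <- function(deriv, y0, times, dt) {
  ny <- length(y0)
  out <- matrix(NA_real_, length(times), ny)
  y <- y0
  out[1L, ] <- y
  for (i in seq_len(length(times) - 1L)) {
    t0 <- times[i]; t1 <- times[i + 1L]
    nsub <- max(1L, ceiling((t1 - t0) / dt))
    h <- (t1 - t0) / nsub
    for (s in seq_len(nsub)) {
      tt <- t0 + (s - 1L) * h
      k1 <- deriv(tt, y)
      k2 <- deriv(tt + h / 2, y + h / 2 * k1)
      k3 <- deriv(tt + h / 2, y + h / 2 * k2)
      k4 <- deriv(tt + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1L, ] <- y
  }
  out
}

#' Simulate a Gd-DTPA tissue curve
#'
#' Two-site exchange: interstitial concentration follows
#' `dCe/dt = (ktrans/ve)(Cp - Ce)`; the measured tissue concentration is
#' `ve Ce + vp Cb` with whole-blood `Cb = (1 - hct) Cp`.  The linear ODE is
#' advanced exactly over each plasma interval (piecewise-linear `Cp`), so no
#' step-size error is introduced.
#'
#' @param plasma_gd plasma Gd [tracer_curve()], mM.
#' @param kin a [gd_kinetics()] object.
#' @param label curve label.
#' @return a [tracer_curve()] of tissue Gd concentration (mM) on the plasma grid.
#' @export
simulate_tissue_gd <- function(plasma_gd, kin, label = "tissue_gd") {
  check_that(inherits(kin, "gd_kinetics"), "kin must be gd_kinetics")
  check_that(nrow(plasma_gd) >= 1L, "plasma curve is empty", "insufficient_data")
  ce <- gd_interstitial(plasma_gd$time_min, plasma_gd$value,
                        if (kin$ktrans > 0) kin$ktrans / kin$ve else 0)
  cb <- (1 - kin$hct) * plasma_gd$value
  tracer_curve(plasma_gd$time_min, kin$ve * ce + kin$vp * cb, label)
}

# Exact update of dCe/dt = a (Cp - Ce) with Cp piecewise linear.
# Vectorised over `a` (one trajectory per rate constant).
gd_interstitial <- function(times, cp, a) {
  n <- length(times)
  na <- length(a)
  ce <- matrix(0, n, na)
  if (n == 1L) return(if (na == 1L) ce[, 1L] else ce)
  pos <- a > 0
  for (i in seq_len(n - 1L)) {
    h <- times[i + 1L] - times[i]
    s <- (cp[i + 1L] - cp[i]) / h
    prev <- ce[i, ]
    nxt <- prev
    if (any(pos)) {
      ap <- a[pos]
      nxt[pos] <- cp[i + 1L] - s / ap +
        (prev[pos] - cp[i] + s / ap) * exp(-ap * h)
    }
    ce[i + 1L, ] <- nxt
  }
  if (na == 1L) ce[, 1L] else ce
}

#' Convert Gd concentration to T1
#'
#' Fast-exchange linear relaxivity model: `1/T1 = 1/T10 + r1 * C`, with `r1`
#' in 1/(mM s) and T1 in ms (the unit conversion is handled internally).
#'
#' @param conc Gd concentration, mM (>= 0); vectorised.
#' @param t10 native T1, ms (> 0).
#' @param r1 relaxivity, 1/(mM s).
#' @return T1 in ms.
#' @export
concentration_to_t1 <- function(conc, t10, r1 = 4.5) {
  check_that(all(t10 > 0), "t10 must be > 0")
  check_that(all(conc >= 0), "conc must be >= 0")
  check_that(r1 > 0, "r1 must be > 0")
  1 / (1 / t10 + (r1 / 1000) * conc)
}

#' Sample a curve at given times with Gaussian noise
#'
#' @param curve a [tracer_curve()] (e.g. a T1-vs-time curve).
#' @param sample_times times within the curve range, minutes.
#' @param noise_sd additive Gaussian noise SD (same units as the curve).
#' @param seed optional integer seed; identical seeds give identical samples.
#' @return numeric vector of sampled values.
#' @export
sample_curve <- function(curve, sample_times, noise_sd = 0, seed = NULL) {
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  v <- interp_curve(curve, sample_times)$value
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  v
}

#' MOLLI-style T1 sampling of myocardium and blood
#'
#' Emulates the protocol's single-slice T1 maps acquired every 10 min: both
#' T1-vs-time curves are linearly interpolated at `sample_times` and
#' additive Gaussian noise of SD `noise_sd` ms is applied.
#'
#' @param t1_myo,t1_blood T1-vs-time [tracer_curve()]s (value = T1 in ms).
#' @param sample_times sampling times, minutes (default every 10 min over the
#'   common range).
#' @param noise_sd T1 noise SD, ms.
#' @param seed optional integer seed.
#' @return a `t1_table`: data.frame with `time_min`, `t1_myo_ms`, `t1_blood_ms`.
#' @export
sample_molli <- function(t1_myo, t1_blood, sample_times = NULL,
                         noise_sd = 0, seed = NULL) {
  if (is.null(sample_times)) {
    lo <- max(t1_myo$time_min[1L], t1_blood$time_min[1L])
    hi <- min(t1_myo$time_min[nrow(t1_myo)], t1_blood$time_min[nrow(t1_blood)])
    sample_times <- seq(ceiling(lo / 10) * 10, hi, by = 10)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  myo <- sample_curve(t1_myo, sample_times, noise_sd, seed = NULL)
  blood <- sample_curve(t1_blood, sample_times, noise_sd, seed = NULL)
  structure(data.frame(time_min = sample_times, t1_myo_ms = myo,
                       t1_blood_ms = blood),
            class = c("t1_table", "data.frame"))
}
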