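# synthetic-data generators: closed forms, ODE oracles, determinism

test_that("plasma curve matches closed-form limits and the ODE oracle", {
  p <- infusion_protocol()
  # zero-elimination limit: linear ramp rate*t/vd
  ramp <- simulate_plasma_curve(p, rate = 4, vd = 200, kel = 0, grid = 1)
  expect_equal(ramp$value[ramp$time_min == 10], 0.2, tolerance = 1e-12)
  # steady-state plateau rate/(vd*kel)
  plateau <- simulate_plasma_curve(p, rate = 4, vd = 200, kel = 0.2, grid = 1)
  expect_equal(plateau$value[nrow(plateau)], 4 / (200 * 0.2), tolerance = 1e-6)
  # fine-step ODE oracle on a 0.1-min grid, 1e-6 relative
  cp <- simulate_plasma_curve(p, rate = 4, vd = 200, kel = 0.02, grid = 0.1)
  sol <- heun_solve(function(t, y) 4 / 200 - 0.02 * y, 0, cp$time_min, dt = 0.002)
  late <- cp$time_min >= 1
  expect_lt(max(abs(cp$value[late] - sol[late, 1]) / sol[late, 1]), 1e-6)
})

test_that("plasma curve validates parameters", {
  p <- infusion_protocol()
  expect_error(simulate_plasma_curve(p, vd = 0), class = "cardiact_invalid_parameter")
  expect_error(simulate_plasma_curve(p, grid = -1), class = "cardiact_invalid_parameter")
  expect_error(simulate_plasma_curve(p, kel = -0.1), class = "cardiact_invalid_parameter")
})

test_that("FDG tissue curve honours trivial limits and the ODE oracle", {
  w <- demo_fdg_world()
  # K1 = 0 -> pure blood signal
  k0 <- fdg_kinetics(K1 = 0, k2 = 0.15, k3 = 0.05, vb = 0.12)
  t0 <- simulate_tissue_fdg(w$plasma, k0)
  expect_equal(t0$value, 0.12 * w$plasma$value, tolerance = 1e-12)
  # suppression_factor = 1 is the identity schedule
  twin <- simulate_tissue_fdg(w$plasma,
                              fdg_kinetics(0.1, 0.15, 0.05, 0.1,
                                           suppression_factor = 1))
  expect_identical(twin$value, w$tissue$value)
  # independent fine-step integrator agrees to 1e-5 relative
  kin <- fdg_kinetics(0.1, 0.15, 0.05, 0.1, suppression_factor = 0.2,
                      transition_tau = 5)
  tis <- simulate_tissue_fdg(w$plasma, kin)
  cp_fun <- approxfun(w$plasma$time_min, w$plasma$value, rule = 2)
  k3t <- function(t) kin$k3 * (1 - (1 - 0.2) * plogis((t - 40) / 5))
  sol <- heun_solve(function(t, y) c(kin$K1 * cp_fun(t) - (kin$k2 + k3t(t)) * y[1],
                                     k3t(t) * y[1]),
                    c(0, 0), w$plasma$time_min, dt = 0.005)
  ct_oracle <- sol[, 1] + sol[, 2] + kin$vb * w$plasma$value
  late <- w$plasma$time_min >= 1
  expect_lt(max(abs(tis$value[late] - ct_oracle[late]) / ct_oracle[late]), 1e-5)
})

test_that("Gd tissue curve: no-exchange, equilibrium and oracle agreement", {
  p <- infusion_protocol()
  cp <- simulate_plasma_curve(p, rate = 4, vd = 200, kel = 0.05, grid = 0.5)
  # ktrans = 0 -> pure plasma (vp) signal
  kin0 <- gd_kinetics(ktrans = 0, ve = 0.3, vp = 0.06, hct = 0.45)
  t0 <- simulate_tissue_gd(cp, kin0)
  expect_equal(t0$value, 0.06 * (1 - 0.45) * cp$value, tolerance = 1e-12)
  # equilibrium: tissue/blood -> ve/(1-hct) + vp on a long plateau
  kin <- gd_kinetics(ktrans = 0.3, ve = 0.48, vp = 0.03, hct = 0.45)
  tis <- simulate_tissue_gd(cp, kin)
  cb_end <- (1 - 0.45) * cp$value[nrow(cp)]
  expect_equal(tis$value[nrow(tis)] / cb_end, 0.48 / (1 - 0.45) + 0.03,
               tolerance = 2e-3)
  # exact stepping vs fine Heun oracle, 1e-5 relative
  kin2 <- gd_kinetics(ktrans = 0.1, ve = 0.48, vp = 0)
  tis2 <- simulate_tissue_gd(cp, kin2)
  cp_fun <- approxfun(cp$time_min, cp$value, rule = 2)
  sol <- heun_solve(function(t, y) (0.1 / 0.48) * (cp_fun(t) - y), 0,
                    cp$time_min, dt = 0.005)
  late <- cp$time_min >= 1
  expect_lt(max(abs(tis2$value[late] - 0.48 * sol[late, 1]) /
                  pmax(0.48 * sol[late, 1], 1e-12)), 1e-5)
  # ve = 0 with ktrans > 0 is degenerate
  expect_error(gd_kinetics(ktrans = 0.1, ve = 0, vp = 0.05),
               class = "cardiact_invalid_parameter")
})

test_that("concentration_to_t1 evaluates the relaxivity relation", {
  expect_identical(concentration_to_t1(0, 1000), 1000)
  expect_equal(concentration_to_t1(0.5, 1000, r1 = 4.5), 1 / (0.001 + 0.00225),
               tolerance = 1e-12)
  # strictly monotone decreasing in concentration
  t1s <- concentration_to_t1(seq(0, 2, by = 0.1), 1200)
  expect_true(all(diff(t1s) < 0))
  expect_error(concentration_to_t1(-1, 1000), class = "cardiact_invalid_parameter")
  expect_error(concentration_to_t1(0.5, 0), class = "cardiact_invalid_parameter")
})

test_that("MOLLI sampling: exact interpolation, determinism, calibrated noise", {
  t1c <- tracer_curve(seq(0, 150, 5), 1100 - seq(0, 150, 5) * 3)
  expect_equal(sample_curve(t1c, c(40, 90, 150)), c(980, 830, 650))
  blood <- tracer_curve(seq(0, 150, 5), 1600 - seq(0, 150, 5) * 5)
  a <- sample_molli(t1c, blood, noise_sd = 20, seed = 7)
  b <- sample_molli(t1c, blood, noise_sd = 20, seed = 7)
  expect_identical(a, b)
  expect_error(sample_curve(t1c, 200), class = "cardiact_range_error")
  # Monte-Carlo: sample SD of the injected noise within 10% of 20 ms
  set.seed(11)
  reps <- replicate(1000, sample_curve(t1c, 90, noise_sd = 20))
  expect_lt(abs(sd(reps) - 20) / 20, 0.1)
})

test_that("trichrome slides hit the requested fibrosis fraction", {
  s0 <- generate_trichrome_slide(c(40, 40), 0, seed = 1)
  expect_true(all(!s0$truth_mask))
  s1 <- generate_trichrome_slide(c(40, 40), 1, seed = 1)
  expect_true(all(s1$truth_mask))
  s <- generate_trichrome_slide(c(80, 80), 0.2, seed = 42)
  expect_gte(s$truth_fraction, 0.195)
  expect_lte(s$truth_fraction, 0.205)
  expect_identical(dim(s$truth_mask), dim(s$pixels)[1:2])
  expect_equal(s$truth_fraction, sum(s$truth_mask) / length(s$truth_mask))
})

test_that("puncta slides: empty case, spot dominance, bit-reproducibility", {
  s0 <- generate_puncta_slide(c(50, 50), 0, background_sd = 100, seed = 3)
  expect_lt(max(s0$pixels), 1000 + 6 * 100)  # background tail only
  s <- generate_puncta_slide(c(60, 60), 12, amplitude = 20000,
                             background_sd = 100, seed = 5)
  centers <- s$pixels[cbind(round(s$truth_spots$row), round(s$truth_spots$col))]
  expect_gt(min(centers), max(s0$pixels))
  s2 <- generate_puncta_slide(c(60, 60), 12, amplitude = 20000,
                              background_sd = 100, seed = 5)
  expect_identical(s$pixels, s2$pixels)
})

test_that("IOT grid: no-penetration and full-penetration limits, monotone filling", {
  p <- infusion_protocol()
  cp <- simulate_plasma_curve(p, rate = 4, vd = 200, kel = 0.02, grid = 0.5)
  frozen <- simulate_iot_grid(100, c(0, 0), 0.5, c(30, 150), cp, seed = 1)
  expect_equal(unname(frozen[1]), unname(frozen[2]))
  expect_equal(unname(frozen[1]), 100)
  open <- simulate_iot_grid(100, c(0.5, 0.5), 0.5, c(30, 150), cp, seed = 1)
  expect_equal(unname(open), c(0, 0))
  # monotone filling across 100 seeds
  for (sd in 1:100) {
    v <- simulate_iot_grid(60, c(0, 0.01), 0.5, c(30, 150), cp, seed = sd)
    expect_lte(v[["t150"]], v[["t30"]])
  }
  expect_error(simulate_iot_grid(0, c(0, 0.01), 0.5, c(30, 150), cp),
               class = "cardiact_invalid_parameter")
})

test_that("simulated curves are non-negative, finite and seed-reproducible", {
  p <- infusion_protocol()
  for (sd in c(1, 2, 3)) {
    cp <- simulate_plasma_curve(p, vd = 200, kel = 0.02, grid = 1,
                                noise_cv = 0.05, seed = sd)
    tis <- simulate_tissue_fdg(cp, fdg_kinetics(suppression_factor = 0.3))
    gd <- simulate_tissue_gd(cp, gd_kinetics())
    for (cv in list(cp, tis, gd)) {
      expect_true(all(is.finite(cv$value)))
      expect_true(all(cv$value >= 0))
    }
    cp2 <- simulate_plasma_curve(p, vd = 200, kel = 0.02, grid = 1,
                                 noise_cv = 0.05, seed = sd)
    expect_identical(cp$value, cp2$value)
  }
})

test_that("suppression strictly lowers the late Patlak slope", {
  base <- demo_fdg_world()
  supp <- simulate_tissue_fdg(base$plasma,
                              fdg_kinetics(0.1, 0.15, 0.05, 0.1,
                                           suppression_factor = 0.3))
  pts_b <- patlak_points(base$tissue, base$plasma)
  pts_s <- patlak_points(supp, base$plasma)
  expect_lt(fit_patlak(pts_s, c(120, 150))$ki, fit_patlak(pts_b, c(120, 150))$ki)
})

test_that("protocol invariants are enforced", {
  expect_error(infusion_protocol(windows = list(c(10, 40), c(30, 90), c(120, 150))),
               class = "cardiact_invalid_parameter")
  expect_error(infusion_protocol(suppression_onset = 70),
               class = "cardiact_invalid_parameter")
  expect_error(infusion_protocol(windows = list(c(10, 40), c(60, 90), c(120, 160))),
               class = "cardiact_invalid_parameter")
})
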