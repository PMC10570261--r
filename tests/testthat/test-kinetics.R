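# Patlak analysis, MRGlu, percent changes

test_that("cumulative_integral is exact on piecewise-linear curves", {
  tt <- seq(0, 20, 2)
  const <- tracer_curve(tt, rep(3, length(tt)))
  expect_equal(cumulative_integral(const)$value, 3 * tt, tolerance = 1e-12)
  ramp <- tracer_curve(tt, 0.5 * tt)
  expect_equal(cumulative_integral(ramp)$value, 0.25 * tt^2, tolerance = 1e-12)
  # curve starting after t = 0: value 0 assumed at the origin
  late <- tracer_curve(c(4, 6), c(2, 2))
  expect_equal(cumulative_integral(late)$value, c(4, 8), tolerance = 1e-12)
})

test_that("cumulative_integral matches a 10x-refined oracle on a smooth curve", {
  f <- function(t) 2 + sin(t / 7) + 0.02 * t
  coarse <- tracer_curve(seq(0, 100, 1), f(seq(0, 100, 1)))
  fine_t <- seq(0, 100, 0.1)
  fine <- tracer_curve(fine_t, f(fine_t))
  ci_coarse <- cumulative_integral(coarse)$value
  ci_fine <- cumulative_integral(fine)$value[match(coarse$time_min, fine_t)]
  sel <- ci_fine > 1
  expect_lt(max(abs(ci_coarse[sel] - ci_fine[sel]) / ci_fine[sel]), 1e-3)
})

test_that("patlak_points handles pure-blood and identity signals", {
  p <- infusion_protocol()
  cp <- simulate_plasma_curve(p, rate = 4, vd = 200, kel = 0.02, grid = 1)
  # Ct = k Cp -> y constant, zero slope
  blood <- tracer_curve(cp$time_min, 0.4 * cp$value)
  pts <- patlak_points(blood, cp)
  expect_equal(unique(round(pts$y, 10)), 0.4)
  expect_equal(fit_patlak(pts, c(10, 150))$ki, 0, tolerance = 1e-10)
  # Ct = Cp -> y identically 1
  pts1 <- patlak_points(cp, cp)
  expect_true(all(abs(pts1$y - 1) < 1e-12))
  # early zero-plasma samples are dropped and counted
  expect_gte(attr(pts, "n_dropped"), 1)
  expect_error(patlak_points(tracer_curve(1:3, c(1, 1, 1)),
                             tracer_curve(1:3, c(0, 0, 0))),
               class = "cardiact_insufficient_data")
})

test_that("fit_patlak reproduces collinear points exactly and enforces windows", {
  x <- seq(10, 80, 5)
  pts <- structure(data.frame(t = x, x = x, y = 0.02 * x + 0.3),
                   class = c("patlak_points", "data.frame"))
  f <- fit_patlak(pts, c(10, 80))
  expect_equal(f$ki, 0.02, tolerance = 1e-12)
  expect_equal(f$intercept, 0.3, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # closed windows: boundary points belong
  expect_equal(fit_patlak(pts, c(10, 20))$n_points, 3)
  err <- tryCatch(fit_patlak(pts, c(81, 100)), error = identity)
  expect_s3_class(err, "cardiact_insufficient_data")
  expect_match(conditionMessage(err), "81")
})

test_that("noiseless simulation recovers the analytic Ki in the late window", {
  w <- demo_fdg_world()  # K1=0.1 k2=0.15 k3=0.05 -> Ki=0.025
  expect_equal(analytic_ki(w$kin), 0.025, tolerance = 1e-12)
  pts <- patlak_points(frame_curve(w$tissue, 3), frame_curve(w$plasma, 3))
  f <- fit_patlak(pts, c(120, 150))
  expect_lt(abs(f$ki - 0.025) / 0.025, 0.02)
  # suppressed twin: late-window ki drops below the before-window ki
  supp <- simulate_tissue_fdg(w$plasma,
                              fdg_kinetics(0.1, 0.15, 0.05, 0.1,
                                           suppression_factor = 0.1))
  pts_s <- patlak_points(frame_curve(supp, 3), frame_curve(w$plasma, 3))
  expect_lt(fit_patlak(pts_s, c(120, 150))$ki, fit_patlak(pts_s, c(10, 40))$ki)
})

test_that("Patlak slope is invariant to rescaling and resampling works", {
  w <- demo_fdg_world()
  pts <- patlak_points(w$tissue, w$plasma)
  scaled <- patlak_points(tracer_curve(w$tissue$time_min, 37 * w$tissue$value),
                          tracer_curve(w$plasma$time_min, 37 * w$plasma$value))
  expect_equal(fit_patlak(scaled, c(60, 150))$ki, fit_patlak(pts, c(60, 150))$ki,
               tolerance = 1e-12)
  # plasma on a different grid is interpolated onto the tissue grid
  coarse_plasma <- tracer_curve(seq(0, 150, 2.5),
                                approx(w$plasma$time_min, w$plasma$value,
                                       seq(0, 150, 2.5))$y)
  pts2 <- patlak_points(w$tissue, coarse_plasma)
  expect_equal(fit_patlak(pts2, c(120, 150))$ki, fit_patlak(pts, c(120, 150))$ki,
               tolerance = 1e-3)
})

test_that("noisy parameter recovery: median relative Ki error < 10%", {
  w <- demo_fdg_world()
  framed_t <- frame_curve(w$tissue, 3)
  framed_p <- frame_curve(w$plasma, 3)
  set.seed(202)
  errs <- replicate(200, {
    noisy <- add_tac_noise(framed_t, 0.05)
    f <- fit_patlak(patlak_points(noisy, framed_p), c(60, 150))
    abs(f$ki - 0.025) / 0.025
  })
  expect_lt(median(errs), 0.10)
})

test_that("mrglu arithmetic and validation", {
  expect_equal(mrglu(0.02, 5.5)$mrglu, 0.11, tolerance = 1e-12)
  expect_equal(mrglu(0, 5.5)$mrglu, 0)
  expect_equal(mrglu(0.02, 5.5, lc = 2)$mrglu, mrglu(0.02, 5.5)$mrglu / 2,
               tolerance = 1e-12)
  expect_error(mrglu(0.02, 5.5, lc = 0), class = "cardiact_invalid_parameter")
  expect_error(mrglu(0.02, -1), class = "cardiact_invalid_parameter")
})

test_that("percent_change truncates toward zero and validates", {
  expect_identical(percent_change(0.109, 0.027), 75)
  expect_identical(percent_change(0.083, 0.007), 91)
  expect_identical(percent_change(1, 1), 0)
  expect_equal(percent_change(0.109, 0.027, rounding = "none"),
               100 * (0.109 - 0.027) / 0.109, tolerance = 1e-12)
  expect_error(percent_change(0, 1), class = "cardiact_invalid_parameter")
  # complement identity on exact-decimal cases
  for (p in c(5, 10, 25, 40, 75, 91)) {
    a <- 8
    expect_identical(percent_change(a, a * (1 - p / 100)), p)
  }
})

test_that("volume_reduction arithmetic", {
  expect_equal(volume_reduction(10, 10), 0)
  expect_equal(volume_reduction(10, 0), 100)
  expect_equal(volume_reduction(3.1, 0.961), 69, tolerance = 1e-9)
  expect_error(volume_reduction(0, 1), class = "cardiact_invalid_parameter")
})

test_that("window-invariance of noiseless Ki past the equilibration transient", {
  # fast-equilibrating kinetics so transient bias is negligible by 60 min
  kin <- fdg_kinetics(0.1, 0.15, 0.05, 0.1)
  w <- demo_fdg_world(kin)
  pts <- patlak_points(frame_curve(w$tissue, 3), frame_curve(w$plasma, 3))
  k_mid <- fit_patlak(pts, c(60, 90))$ki
  k_late <- fit_patlak(pts, c(120, 150))$ki
  expect_lt(abs(k_mid - k_late) / k_late, 0.02)
})
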