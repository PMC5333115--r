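test_that("g-factor computation follows the unit conversions and sign", {
  expect_equal(compute_g_factor(500, 0)$value, 0)
  # hand conversion: (32.98/32980) / (1000/1000) = 1e-3
  expect_equal(compute_g_factor(1000, 32.98)$value, 1e-3,
               tolerance = 1e-12)
  expect_equal(compute_g_factor(1000, -32.98)$value,
               -compute_g_factor(1000, 32.98)$value)
  expect_error(compute_g_factor(0, 5), "degenerate")
  expect_error(compute_g_factor(-2, 5), "degenerate")
})

test_that("ee estimation is the g ratio with a configuration call", {
  g_ref <- compute_g_factor(1000, 32.98)
  est <- estimate_ee(g_ref, g_ref, "R")
  expect_equal(est$ee, 1)
  expect_equal(est$ee_percent, 100)
  expect_equal(est$dominant, "R")

  est0 <- estimate_ee(compute_g_factor(800, 0), g_ref, "R")
  expect_equal(est0$ee, 0)
  expect_equal(est0$dominant, "racemic")

  g_half <- compute_g_factor(1000, -0.5 * 32.98)
  est_s <- estimate_ee(g_half, g_ref, "R")
  expect_equal(est_s$ee, -0.5)
  expect_equal(est_s$dominant, "S")
  expect_equal(est_s$ee_percent, 50)

  # contract cases
  g_other_wl <- compute_g_factor(1000, 32.98, wavelength = 280)
  expect_error(estimate_ee(g_other_wl, g_ref), "wavelength mismatch")
  g_over <- compute_g_factor(1000, 1.10 * 32.98)
  expect_error(estimate_ee(g_over, g_ref), "inconsistent reference")
  g_slight <- compute_g_factor(1000, 1.02 * 32.98)
  expect_warning(est_c <- estimate_ee(g_slight, g_ref), "clipping")
  expect_equal(est_c$ee, 1)
})

test_that("conversion ratio is response-corrected area percent", {
  expect_equal(conversion_ratio(0, 10)$cr, 100)
  expect_equal(conversion_ratio(50, 50)$cr, 50)
  # product 300, substrate 100, response factor 1.5 -> 100*200/300
  expect_equal(conversion_ratio(100, 300, 1.5)$cr, 100 * 200 / 300,
               tolerance = 1e-12)
  expect_error(conversion_ratio(0, 0), "degenerate")
})

test_that("calibration fit matches closed-form least squares", {
  x <- 0:4
  fit <- fit_calibration(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # hand OLS on (0,0), (1,1), (2,3): slope 1.5, intercept -1/6
  fit2 <- fit_calibration(c(0, 1, 2), c(0, 1, 3))
  expect_equal(fit2$slope, 1.5, tolerance = 1e-12)
  expect_equal(fit2$intercept, -1 / 6, tolerance = 1e-12)

  # constant response: slope 0, r^2 flagged undefined
  fit3 <- fit_calibration(c(0, 1, 2), c(4, 4, 4))
  expect_equal(fit3$slope, 0, tolerance = 1e-12)
  expect_false(fit3$r_squared_defined)

  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "degenerate x")
  expect_error(fit_calibration(c(0, 1), c(0, 1)), "at least 3")
})

test_that("linearity checks mirror the validation protocol", {
  f_R <- seq(0, 1, by = 0.25)
  uv_fit <- fit_calibration(f_R, rep(500, 5))
  expect_true(check_linearity(uv_fit, "uv-constant")$pass)

  ecd_fit <- fit_calibration(f_R, 100 * (2 * f_R - 1))
  expect_true(check_linearity(ecd_fit, "ecd-linear")$pass)

  # UV slope drifting 10% of the mean over the span fails at 5% tolerance
  drift_fit <- fit_calibration(f_R, 500 + 50 * f_R)
  expect_false(check_linearity(drift_fit, "uv-constant",
                               slope_tolerance = 0.05)$pass)
})

test_that("g-factor concentration invariance uses population CV", {
  expect_equal(g_concentration_invariance(rep(1e-3, 4))$cv, 0)
  # hand value: sd_pop/mean of (1.0, 1.1, 0.9)e-3
  res <- g_concentration_invariance(c(1.0e-3, 1.1e-3, 0.9e-3))
  expect_equal(res$cv, sqrt(0.02 / 3), tolerance = 1e-9)
  expect_equal(res$cv, 0.0816, tolerance = 1e-3)
  expect_error(g_concentration_invariance(c(1e-9, -1e-9, 0) * 0),
               "undefined CV")
  expect_error(g_concentration_invariance(c(1e-3, 1e-3)), "at least 3")
})

test_that("concentration cancels in g: estimated ee is stable over a 10x range", {
  g_ref <- reference_g()
  ees <- vapply(c(0.2, 0.5, 1, 2), function(conc) {
    gen <- gen_chromatogram(mixture_spec(total_conc = conc, f_R = 0.8),
                            "achiral")
    estimate_ee(measure_g_product(gen), g_ref)$ee
  }, numeric(1))
  expect_lt(max(ees) - min(ees), 0.01)
  expect_equal(mean(ees), 0.6, tolerance = 0.01)
})

test_that("mirror consistency: swapping R and S negates g and flips the call", {
  g_ref <- reference_g()
  gen_R <- gen_chromatogram(mixture_spec(f_R = 0.9), "achiral")
  gen_S <- gen_chromatogram(mixture_spec(f_R = 0.1), "achiral")
  g_R <- measure_g_product(gen_R); g_S <- measure_g_product(gen_S)
  expect_equal(g_S$value, -g_R$value, tolerance = 1e-9)
  expect_equal(estimate_ee(g_R, g_ref)$dominant, "R")
  expect_equal(estimate_ee(g_S, g_ref)$dominant, "S")
})

test_that("racemate g is null relative to the pure enantiomer", {
  g_ref <- reference_g()
  gen <- gen_chromatogram(mixture_spec(f_R = 0.5), "achiral")
  g_rac <- measure_g_product(gen)
  expect_lt(abs(g_rac$value), 1e-3 * abs(g_ref$value))
})
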