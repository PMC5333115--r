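test_that("Boltzmann weights follow the closed forms and normalize", {
  expect_equal(boltzmann_weights(rep(1.2, 4)), rep(0.25, 4))
  # energy gap of kT*ln(2) gives a 2:1 population ratio
  kT <- 0.0019872 * 298.15
  expect_equal(boltzmann_weights(c(0, kT * log(2))), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  # zero-temperature limit concentrates all weight in the minimum
  expect_equal(boltzmann_weights(c(0, 1), temperature = 1), c(1, 0),
               tolerance = 1e-9)
  expect_error(boltzmann_weights(numeric(0)), "empty")

  # property: normalization and energy monotonicity under random inputs
  set.seed(11)
  for (i in 1:20) {
    e <- runif(sample(2:8, 1), 0, 5)
    w <- boltzmann_weights(e, temperature = runif(1, 50, 600))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(diff(w[order(e)]) <= 1e-15))
  }
})

test_that("single-transition spectrum matches the band-shape closed form", {
  cs <- single_transition(energy_ev = 4.9594, strength = 10)
  sp <- simulate_ecd(cs, band_shape_params(grid_min = 180, grid_max = 400,
                                           grid_step = 0.25))
  # peak value at E = E_i: E_i * R_i * 1e-40 / (2.297e-39 * sqrt(pi) * sigma)
  peak_expected <- 4.9594 * 10e-40 / (2.297e-39 * sqrt(pi) * 0.35)
  expect_equal(peak_expected, 3.4804, tolerance = 1e-4)
  at250 <- sp$delta_epsilon[sp$wavelength == 250]
  expect_equal(at250, peak_expected, tolerance = 1e-6)
  # maximum sits at the transition wavelength
  expect_equal(sp$wavelength[which.max(sp$delta_epsilon)],
               1239.842 / 4.9594, tolerance = 0.3)
})

test_that("band area over energy recovers the Gaussian normalization", {
  cs <- single_transition(energy_ev = 4.9594, strength = 10)
  sigma <- 0.35
  # wavelength grid covering E_i +/- 5 sigma
  lam <- 1239.842 / c(4.9594 + 5 * sigma, 4.9594 - 5 * sigma)
  sp <- simulate_ecd(cs, band_shape_params(sigma = sigma,
                                           grid_min = lam[1],
                                           grid_max = lam[2],
                                           grid_step = 0.1))
  energy <- 1239.842 / sp$wavelength
  ord <- order(energy)
  area <- pracma::trapz(energy[ord], sp$delta_epsilon[ord])
  expect_equal(area, 4.9594 * 10e-40 / 2.297e-39, tolerance = 0.005)
})

test_that("spectra are antisymmetric under enantiomer mirroring and zero without rotational strength", {
  cs <- gen_transition_table(n_conformers = 4, n_transitions = 15,
                             seed = 3)
  params <- band_shape_params(grid_min = 200, grid_max = 380,
                              grid_step = 2)
  sp <- simulate_ecd(cs, params)
  sp_mirror <- simulate_ecd(mirror_transitions(cs), params)
  expect_equal(sp_mirror$delta_epsilon, -sp$delta_epsilon,
               tolerance = 1e-12)

  cs0 <- cs; cs0$rotational_strength_1e40cgs <- 0
  expect_true(all(simulate_ecd(cs0, params)$delta_epsilon == 0))
})

test_that("grid refinement leaves values at common points unchanged", {
  cs <- gen_transition_table(n_conformers = 3, n_transitions = 10,
                             seed = 5)
  coarse <- simulate_ecd(cs, band_shape_params(grid_min = 200,
                                               grid_max = 360,
                                               grid_step = 2))
  fine <- simulate_ecd(cs, band_shape_params(grid_min = 200,
                                             grid_max = 360,
                                             grid_step = 1))
  common <- match(coarse$wavelength, fine$wavelength)
  expect_equal(fine$delta_epsilon[common], coarse$delta_epsilon,
               tolerance = 1e-14)
})

test_that("configuration assignment compares Cotton-effect signs", {
  sp_R <- simulate_ecd(single_transition(energy_ev = 1239.842 / 250,
                                         strength = 10),
                       band_shape_params(grid_min = 200, grid_max = 320,
                                         grid_step = 0.5))
  expect_equal(assign_configuration("positive", 250, sp_R)$configuration,
               "R")
  expect_equal(assign_configuration("negative", 250, sp_R)$configuration,
               "S")
  # node: simulated spectrum ~ 0 at the probe wavelength
  sp0 <- sp_R; sp0$delta_epsilon <- 0 * sp0$delta_epsilon
  expect_error(assign_configuration("positive", 250, sp0),
               "indeterminate")
  expect_error(assign_configuration("positive", 500, sp_R), "outside")
})

test_that("transition tables and spectra round-trip through CSV", {
  cs <- gen_transition_table(n_conformers = 2, n_transitions = 5, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_table(cs, path)
  back <- read_transition_table(path)
  expect_equal(back$energy_ev, cs$energy_ev, tolerance = 1e-9)
  expect_equal(back$rotational_strength_1e40cgs,
               cs$rotational_strength_1e40cgs, tolerance = 1e-9)

  sp <- simulate_ecd(cs, band_shape_params(grid_min = 220, grid_max = 320,
                                           grid_step = 5))
  spath <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, spath)
  expect_equal(read_spectrum(spath)$delta_epsilon, sp$delta_epsilon,
               tolerance = 1e-9)
})

test_that("conformer sets enforce their invariants", {
  df <- data.frame(conformer_id = "a", relative_energy_kcal = 0.5,
                   energy_ev = 4, rotational_strength_1e40cgs = 1)
  expect_error(conformer_set(df), "zero minimum")
  df$relative_energy_kcal <- -1
  expect_error(conformer_set(df), ">= 0")
  df$relative_energy_kcal <- 0; df$energy_ev <- -2
  expect_error(conformer_set(df), "positive")
  expect_error(conformer_set(df[, 1:3]), "missing column")
})
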