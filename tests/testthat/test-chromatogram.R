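test_that("chromatogram constructor enforces its invariants", {
  expect_s3_class(chromatogram(0:2, c(0, 5, 0), c(0, 1, 0)),
                  "chromatogram")
  expect_error(chromatogram(c(0, 1, 1.5), rep(0, 3), rep(0, 3)),
               "uniform")
  expect_error(chromatogram(c(0, 1, 0.5), rep(0, 3), rep(0, 3)),
               "increasing")
  expect_error(chromatogram(0:2, c(0, 5), c(0, 1, 0)), "equal length")
  expect_error(chromatogram(0:1, c(0, 0), c(0, 0), wavelength = -1),
               "wavelength")
  expect_error(chromatogram(0, 0, 0), "at least 2")
})

test_that("CSV reader parses data and metadata, and errors name the missing column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#sample_id=inj1", "#column=achiral", "time,uv,ecd",
               "0,0,0", "1,5,1", "2,0,0"), path)
  ch <- read_chromatogram(path)
  expect_length(ch$time, 3)
  expect_equal(ch$uv, c(0, 5, 0))
  expect_equal(ch$meta$sample_id, "inj1")
  expect_equal(ch$meta$column, "achiral")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,uv", "0,0", "1,1"), bad)
  expect_error(read_chromatogram(bad), "missing column: ecd")
})

test_that("write/read round trip reproduces traces to 1e-9", {
  gen <- gen_chromatogram(mixture_spec(f_R = 0.8, substrate_conc = 0.3),
                          "achiral", step = 0.05,
                          detector = detector_model(noise_sd_rel = 0.01,
                                                    seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(gen$chrom, path)
  back <- read_chromatogram(path)
  expect_equal(back$time, gen$chrom$time, tolerance = 1e-9)
  expect_equal(back$uv, gen$chrom$uv, tolerance = 1e-9)
  expect_equal(back$ecd, gen$chrom$ecd, tolerance = 1e-9)
  expect_equal(back$wavelength, gen$chrom$wavelength)
})

test_that("detect_peaks returns nothing on a flat trace and finds synthetic Gaussians", {
  t <- seq(0, 10, by = 0.01)
  flat <- chromatogram(t, rep(0, length(t)), rep(0, length(t)))
  expect_equal(nrow(detect_peaks(flat, default_params())), 0)

  # single Gaussian: closed-form area A * sigma * sqrt(2*pi)
  uv <- 100 * exp(-(t - 5)^2 / (2 * 0.1^2))
  ch <- chromatogram(t, uv, 0 * uv)
  pk <- detect_peaks(ch, default_params())
  expect_equal(nrow(pk), 1)
  expect_equal(pk$uv_area, 100 * 0.1 * sqrt(2 * pi), tolerance = 0.01)
  expect_lt(abs(pk$rt - 5), 0.01 + 1e-12)

  # two baseline-resolved Gaussians 5 min apart
  uv2 <- 100 * exp(-(t - 2)^2 / (2 * 0.1^2)) +
    40 * exp(-(t - 7)^2 / (2 * 0.1^2))
  ch2 <- chromatogram(t, uv2, 0 * uv2)
  pk2 <- detect_peaks(ch2, default_params())
  expect_equal(nrow(pk2), 2)
  expect_lt(max(abs(pk2$rt - c(2, 7))), 0.01 + 1e-12)
})

test_that("generator peak count is recovered for well-separated peaks", {
  for (f_R in c(0, 0.3, 1)) {
    gen <- gen_chromatogram(mixture_spec(f_R = f_R, substrate_conc = 0.5),
                            "achiral")
    pk <- detect_peaks(gen$chrom, default_params())
    expect_equal(nrow(pk), 2)
    expect_lt(max(abs(sort(pk$rt) - sort(unname(gen$truth$rts)))),
              time_step(gen$chrom) + 1e-12)
  }
  gen3 <- gen_chromatogram(mixture_spec(f_R = 0.7, substrate_conc = 0.2),
                           "chiral", step = 0.02)
  expect_equal(nrow(detect_peaks(gen3$chrom, default_params())), 3)
})

test_that("integrate_window matches hand integrals and keeps ECD sign", {
  t <- seq(0, 5, by = 0.001)
  zero <- chromatogram(t, rep(0, length(t)), rep(0, length(t)))
  expect_equal(unname(integrate_window(zero, 1, 3)), c(0, 0))

  # rectangle pulse 10 mAU over 2 min on zero baseline
  uv <- ifelse(t >= 1 & t <= 3, 10, 0)
  rect <- chromatogram(t, uv, -uv)
  areas <- integrate_window(rect, 0, 5)
  expect_equal(areas[["uv_area"]], 20, tolerance = 1e-3)
  # ECD = -UV implies ecd_area = -uv_area exactly (linearity)
  expect_equal(areas[["ecd_area"]], -areas[["uv_area"]], tolerance = 1e-12)

  expect_error(integrate_window(rect, -1, 3), "outside")
  expect_error(integrate_window(rect, 4, 6), "outside")
  expect_error(integrate_window(rect, 3, 1), "t_start")
})

test_that("integration is linear in the traces", {
  t <- seq(0, 4, by = 0.01)
  f <- exp(-(t - 1.5)^2 / 0.02)
  g <- cos(t)
  alpha <- 2.5; beta <- -1.3
  mk <- function(y) chromatogram(t, y, y)
  a_comb <- integrate_window(mk(alpha * f + beta * g), 0.5, 3.5)
  a_f <- integrate_window(mk(f), 0.5, 3.5)
  a_g <- integrate_window(mk(g), 0.5, 3.5)
  expect_equal(a_comb[["uv_area"]],
               alpha * a_f[["uv_area"]] + beta * a_g[["uv_area"]],
               tolerance = 1e-9)
})

test_that("rolling-minimum baseline recovers areas under curved drift", {
  # a slow curved baseline that a whole-trace endpoint line cannot model
  t <- seq(0, 10, by = 0.01)
  baseline <- 20 * sin(pi * t / 10)
  peak <- 100 * exp(-(t - 5)^2 / (2 * 0.1^2))
  ch <- chromatogram(t, baseline + peak, 0 * t)
  pk <- detect_peaks(ch, peak_params(min_height = 5, min_prominence = 5,
                                     baseline_mode = "rolling-minimum"))
  expect_equal(nrow(pk), 1)
  # opening-based baselines carry a small positive bias where the baseline
  # slopes under the peak; a few percent is the realistic accuracy
  expect_equal(pk$uv_area, 100 * 0.1 * sqrt(2 * pi), tolerance = 0.05)
  expect_lt(abs(pk$rt - 5), 0.02)
})
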