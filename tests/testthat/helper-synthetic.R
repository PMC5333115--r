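# shared fixtures: generators are cheap, so everything is built in code

# smoothing plus a prominence floor well above the 1% detector noise keeps
# flank noise spikes from registering as peaks
default_params <- function() peak_params(min_height = 5,
                                         min_prominence = 20,
                                         smoothing_window = 5)

# g-factor of the product peak of a generated injection
measure_g_product <- function(gen, params = default_params(),
                              product_window = c(5, 7.5)) {
  pk <- detect_peaks(gen$chrom, params)
  inside <- pk$rt >= product_window[1] & pk$rt <= product_window[2]
  stopifnot(any(inside))
  prod <- pk[inside, ][1, ]
  compute_g_factor(prod$uv_area, prod$ecd_area,
                   wavelength = gen$chrom$wavelength)
}

# reference g measured from a noise-free pure-R injection
reference_g <- function(detector = detector_model()) {
  detector$noise_sd_rel <- 0
  gen <- gen_chromatogram(mixture_spec(f_R = 1), "achiral",
                          detector = detector)
  measure_g_product(gen)
}

# single-transition conformer set for closed-form oracles
single_transition <- function(energy_ev = 4.9594, strength = 10) {
  conformer_set(data.frame(conformer_id = "c1", relative_energy_kcal = 0,
                           energy_ev = energy_ev,
                           rotational_strength_1e40cgs = strength))
}
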