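# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv()))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specify an enantiomer mixture for the chromatogram generator
#'
#' @param total_conc Total product concentration (arbitrary units, > 0).
#' @param f_R Fraction of the reference (R) enantiomer in the product,
#'   in [0, 1]; the true signed ee is `2 * f_R - 1`.
#' @param substrate_conc Remaining substrate concentration (>= 0).
#' @return A list of class `mixture_spec` with the fields above plus
#'   `ee_true`.
#' @export
mixture_spec <- function(total_conc = 1, f_R = 0.5, substrate_conc = 0) {
  stopifnot(total_conc > 0, f_R >= 0, f_R <= 1, substrate_conc >= 0)
  structure(list(total_conc = total_conc, f_R = f_R,
                 substrate_conc = substrate_conc, ee_true = 2 * f_R - 1),
            class = "mixture_spec")
}

#' Detector model for the chromatogram generator
#'
#' @param uv_response UV response in mAU per concentration unit (> 0).
#' @param g_pure Dissymmetry factor of the pure reference enantiomer at the
#'   detection wavelength (dimensionless, dA/A scale). A default of 1e-3 is
#'   typical of allowed electronic transitions of organic chromophores.
#' @param noise_sd_rel Relative (multiplicative) noise sd per point on each
#'   channel (>= 0).
#' @param baseline_drift Linear UV baseline drift, mAU per minute.
#' @param seed Integer RNG seed or NULL.
#' @return A list of class `detector_model`.
#' @export
detector_model <- function(uv_response = 100, g_pure = 1e-3,
                           noise_sd_rel = 0, baseline_drift = 0,
                           seed = NULL) {
  stopifnot(uv_response > 0, noise_sd_rel >= 0)
  structure(list(uv_response = uv_response, g_pure = g_pure,
                 noise_sd_rel = noise_sd_rel,
                 baseline_drift = baseline_drift, seed = seed),
            class = "detector_model")
}

#' Chromatographic peak shape
#'
#' Unit-area Gaussian, or exponentially modified Gaussian when `tau > 0`.
#' Peak area carries the injected amount (detector response integrates the
#' eluting mass), so a species' UV area is `concentration * uv_response`
#' regardless of how broad its band is; the width only sets the height.
#'
#' @param rt Apex retention time, minutes.
#' @param sigma_t Gaussian width, minutes (> 0).
#' @param tau Exponential tail constant, minutes (>= 0; 0 = pure Gaussian).
#' @return A list of class `peak_shape`.
#' @export
peak_shape <- function(rt, sigma_t = 0.1, tau = 0) {
  stopifnot(sigma_t > 0, tau >= 0)
  structure(list(rt = rt, sigma_t = sigma_t, tau = tau),
            class = "peak_shape")
}

# evaluate a peak_shape on a time grid; unit area in either branch
eval_shape <- function(shape, time) {
  s <- shape$sigma_t; rt <- shape$rt; tau <- shape$tau
  if (tau <= 0)
    return(exp(-(time - rt)^2 / (2 * s^2)) / (s * sqrt(2 * pi)))
  z <- (s / tau - (time - rt) / s) / sqrt(2)
  (1 / (2 * tau)) *
    exp(0.5 * (s / tau)^2 - (time - rt) / tau) * pracma::erfc(z)
}

#' Generate a synthetic dual-channel chromatogram with known ground truth
#'
#' Emulates the two measurement regimes of online UV/ECD detection. On an
#' achiral (reverse-phase) column the two product enantiomers co-elute as
#' one peak; on a chiral column they resolve into separate peaks. The UV
#' trace is the concentration-weighted sum of unit-area peak shapes times
#' the detector response (plus optional linear drift and multiplicative
#' noise), so each species' noise-free UV area is
#' `concentration * uv_response` mAU·min. The ECD trace carries only the
#' product's chiral signal, scaled by
#' `(c_R - c_S) * uv_response * g_pure * 32.98` (the
#' ellipticity-per-absorbance constant over the mAU scale), so that
#' [compute_g_factor()] over the product peak recovers `g_pure * ee_true`
#' in the noise-free limit. The substrate is achiral and ECD-silent.
#'
#' @param mix A [mixture_spec()].
#' @param column `"achiral"` (co-eluting product peak) or `"chiral"`
#'   (resolved enantiomer peaks).
#' @param shapes Named list of [peak_shape()]s: `substrate` and `product`
#'   for the achiral column; `substrate`, `R` and `S` for the chiral
#'   column. Defaults place the product near 6 min (achiral) and the
#'   enantiomers near 23.78 / 28.71 min (chiral).
#' @param detector A [detector_model()].
#' @param duration Run length, minutes.
#' @param step Sampling step, minutes.
#' @param wavelength Detection wavelength, nm.
#' @param ellipticity_to_dA,mau_to_A Unit constants, matching
#'   [compute_g_factor()].
#' @return A list with `chrom` (the [chromatogram()]) and `truth` — the
#'   ground-truth record (`f_R`, `ee_true`, `g_product` = g_pure*ee_true,
#'   `cr_true`, per-species retention times and noise-free areas).
#' @export
gen_chromatogram <- function(mix, column = c("achiral", "chiral"),
                             shapes = NULL,
                             detector = detector_model(),
                             duration = NULL, step = 0.01,
                             wavelength = 250,
                             ellipticity_to_dA = 32980, mau_to_A = 1000) {
  column <- match.arg(column)
  stopifnot(inherits(mix, "mixture_spec"), inherits(detector,
                                                    "detector_model"),
            step > 0)
  if (is.null(shapes)) {
    shapes <- if (column == "achiral") {
      list(substrate = peak_shape(3.5, 0.08),
           product = peak_shape(6.0, 0.10))
    } else {
      list(substrate = peak_shape(12.0, 0.15),
           R = peak_shape(23.78, 0.25), S = peak_shape(28.71, 0.25))
    }
  }
  need <- if (column == "achiral") c("substrate", "product")
          else c("substrate", "R", "S")
  if (!all(need %in% names(shapes)))
    stop("shapes must contain: ", paste(need, collapse = ", "))
  if (is.null(duration))
    duration <- max(vapply(shapes, function(s)
      s$rt + 6 * s$sigma_t + 6 * s$tau, numeric(1))) + 1
  for (s in shapes[need])
    if (s$rt - 4 * s$sigma_t < 0 || s$rt + 4 * s$sigma_t > duration)
      warning("peak at ", s$rt, " min extends beyond the run window")

  time <- seq(0, duration, by = step)
  ur <- detector$uv_response
  c_R <- mix$total_conc * mix$f_R
  c_S <- mix$total_conc * (1 - mix$f_R)
  ecd_k <- detector$g_pure * ur * ellipticity_to_dA / mau_to_A

  uv <- mix$substrate_conc * ur * eval_shape(shapes$substrate, time)
  ecd <- numeric(length(time))
  if (column == "achiral") {
    prod_shape <- eval_shape(shapes$product, time)
    uv <- uv + mix$total_conc * ur * prod_shape
    ecd <- ecd + (c_R - c_S) * ecd_k * prod_shape
  } else {
    shape_R <- eval_shape(shapes$R, time)
    shape_S <- eval_shape(shapes$S, time)
    uv <- uv + c_R * ur * shape_R + c_S * ur * shape_S
    ecd <- ecd + c_R * ecd_k * shape_R - c_S * ecd_k * shape_S
  }

  uv <- uv + detector$baseline_drift * time
  if (detector$noise_sd_rel > 0) {
    noisy <- with_seed(detector$seed, {
      list(uv = uv * (1 + stats::rnorm(length(uv), 0,
                                       detector$noise_sd_rel)),
           ecd = ecd * (1 + stats::rnorm(length(ecd), 0,
                                         detector$noise_sd_rel)))
    })
    uv <- noisy$uv; ecd <- noisy$ecd
  }

  truth <- list(
    column = column, f_R = mix$f_R, ee_true = mix$ee_true,
    g_pure = detector$g_pure,
    g_product = detector$g_pure * mix$ee_true,
    cr_true = 100 * mix$total_conc /
      (mix$total_conc + mix$substrate_conc),
    rts = vapply(shapes, function(s) s$rt, numeric(1)),
    uv_areas = if (column == "achiral")
      c(substrate = mix$substrate_conc * ur, product = mix$total_conc * ur)
    else
      c(substrate = mix$substrate_conc * ur, R = c_R * ur, S = c_S * ur))

  list(chrom = chromatogram(time, uv, ecd, wavelength = wavelength,
                            meta = list(column = column)),
       truth = truth)
}

#' Generate a synthetic conformer transition table
#'
#' Produces TDDFT-like output for a pseudo-molecule: `n_conformers`
#' conformers with relative energies in [0, 3] kcal/mol (minimum forced to
#' 0) and `n_transitions` transitions each, with excitation energies drawn
#' uniformly over `energy_range` and rotational strengths from a centred
#' normal of sd `strength_scale`. The mirror-image enantiomer's table is
#' the exact negation of the rotational strengths ([mirror_transitions()]).
#'
#' @param n_conformers,n_transitions Counts (>= 1).
#' @param energy_range Excitation-energy range, eV.
#' @param strength_scale Rotational-strength sd, 1e-40 cgs.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A [conformer_set()].
#' @export
gen_transition_table <- function(n_conformers = 5, n_transitions = 20,
                                 energy_range = c(3.5, 6.5),
                                 strength_scale = 20, seed = NULL) {
  stopifnot(n_conformers >= 1, n_transitions >= 1,
            energy_range[1] > 0, energy_range[2] > energy_range[1])
  with_seed(seed, {
    rel <- stats::runif(n_conformers, 0, 3)
    rel <- rel - min(rel)
    rows <- lapply(seq_len(n_conformers), function(k) {
      data.frame(
        conformer_id = sprintf("conf%02d", k),
        relative_energy_kcal = rel[k],
        energy_ev = sort(stats::runif(n_transitions, energy_range[1],
                                      energy_range[2])),
        oscillator_strength = abs(stats::rnorm(n_transitions, 0, 0.1)),
        rotational_strength_1e40cgs = stats::rnorm(n_transitions, 0,
                                                   strength_scale))
    })
    conformer_set(do.call(rbind, rows))
  })
}

#' Mirror a transition table (the enantiomer's spectrum)
#' @param cs A `conformer_set`.
#' @return The same set with every rotational strength negated.
#' @export
mirror_transitions <- function(cs) {
  cs$rotational_strength_1e40cgs <- -cs$rotational_strength_1e40cgs
  cs
}

#' Generate orthogonal-array responses from a known additive effect model
#'
#' Response per run = `grand_mean` + per-factor level effect + Gaussian
#' noise. With zero noise, [range_analysis()] recovers each factor's true
#' effect span and argmax level exactly (balanced design).
#'
#' @param design An `orthogonal_design`.
#' @param effects Named list (one entry per factor) of length-3 numeric
#'   level effects.
#' @param grand_mean Baseline response.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param seed Integer seed or NULL.
#' @param response_name Name of the response column (default `"y"`).
#' @return A response data frame (`run`, factor levels, response) aligned
#'   with the design.
#' @export
gen_oa_responses <- function(design, effects, grand_mean = 50,
                             noise_sd = 0, seed = NULL,
                             response_name = "y") {
  fac <- design$factor_names
  stopifnot(setequal(names(effects), fac),
            all(vapply(effects, length, 1L) == 3), noise_sd >= 0)
  arr <- design$array
  y <- rep(grand_mean, nrow(arr))
  for (f in fac) y <- y + effects[[f]][arr[, f]]
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  out <- data.frame(run = seq_len(nrow(arr)), arr[, fac, drop = FALSE])
  out[[response_name]] <- y
  validate_response_table(out, design)
}
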