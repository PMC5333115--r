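# eV <-> nm conversion constant (hc in eV.nm)
EV_NM <- 1239.842
# Boltzmann constant in kcal/(mol.K)
KB_KCAL <- 0.0019872
# standard delta-epsilon band-shape prefactor denominator (cgs)
DELTA_EPS_CONST <- 2.297e-39

#' Construct a conformer transition set
#'
#' Holds TDDFT-style output for an ensemble of conformers of one species:
#' per conformer a relative energy (kcal/mol, minimum 0 across the set) and
#' a table of electronic transitions (excitation energy in eV, rotational
#' strength in 1e-40 cgs, optional oscillator strength).
#'
#' @param df Data frame with columns `conformer_id`, `relative_energy_kcal`,
#'   `energy_ev`, `rotational_strength_1e40cgs` and optionally
#'   `oscillator_strength`.
#' @return `df` validated, with class `conformer_set`.
#' @export
conformer_set <- function(df) {
  need <- c("conformer_id", "relative_energy_kcal", "energy_ev",
            "rotational_strength_1e40cgs")
  for (col in need)
    if (!col %in% names(df)) stop("missing column: ", col)
  if (!nrow(df)) stop("conformer set must contain at least one transition")
  if (any(df$energy_ev <= 0)) stop("transition energies must be positive")
  if (any(df$relative_energy_kcal < 0))
    stop("relative conformer energies must be >= 0")
  rel <- tapply(df$relative_energy_kcal, df$conformer_id, function(e) e[1])
  if (min(rel) > 1e-9)
    stop("relative energies must include a zero minimum conformer")
  if (!"oscillator_strength" %in% names(df))
    df$oscillator_strength <- NA_real_
  class(df) <- c("conformer_set", "data.frame")
  df
}

#' Read / write a conformer transition table (CSV)
#'
#' Plain CSV with columns `conformer_id, relative_energy_kcal, energy_ev,
#' rotational_strength_1e40cgs, oscillator_strength`.
#'
#' @param path File path.
#' @return For the reader, a validated [conformer_set()].
#' @export
read_transition_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  conformer_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_transition_table
#' @param cs A `conformer_set`.
#' @export
write_transition_table <- function(cs, path) {
  utils::write.csv(as.data.frame(cs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Band-shape parameters for ECD spectrum simulation
#'
#' @param sigma Gaussian width in eV, used as sigma in
#'   `exp(-((E - E_i)/sigma)^2)` (default 0.35).
#' @param grid_min,grid_max Wavelength grid bounds in nm.
#' @param grid_step Grid step in nm.
#' @param temperature Boltzmann-averaging temperature in K (default 298.15).
#' @return A list of class `band_shape_params`.
#' @export
band_shape_params <- function(sigma = 0.35, grid_min = 180, grid_max = 400,
                              grid_step = 1, temperature = 298.15) {
  stopifnot(sigma > 0, grid_min < grid_max, grid_step > 0, temperature > 0)
  structure(list(sigma = sigma, grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step, temperature = temperature),
            class = "band_shape_params")
}

#' Boltzmann weights of conformers from relative energies
#'
#' `w_i = exp(-dE_i / kT) / sum_j exp(-dE_j / kT)` with
#' `kT = 0.0019872 kcal mol^-1 K^-1 * T`.
#'
#' @param relative_energies Relative energies in kcal/mol (>= 1 value).
#' @param temperature Temperature in K (> 0).
#' @return Numeric weights summing to 1.
#' @export
boltzmann_weights <- function(relative_energies, temperature = 298.15) {
  if (!length(relative_energies)) stop("empty energy list")
  stopifnot(temperature > 0)
  # subtract the minimum for numerical stability; cancels in the ratio
  e <- relative_energies - min(relative_energies)
  w <- exp(-e / (KB_KCAL * temperature))
  w / sum(w)
}

#' Simulate an ECD spectrum from conformer transitions
#'
#' Each transition contributes a Gaussian band in energy space,
#' `delta_eps(E) = 1/(2.297e-39 * sqrt(pi) * sigma) *
#'   sum_i E_i * R_i * 1e-40 * exp(-((E - E_i)/sigma)^2)`
#' with `E`, `E_i` in eV and `R_i` in 1e-40 cgs. Conformer spectra are
#' combined with Boltzmann weights from their relative energies, and the
#' result is evaluated pointwise on a wavelength grid via
#' `E = 1239.842 / lambda` (no discretization of the formula, so grid
#' refinement leaves values at common points unchanged).
#'
#' @param conformers A [conformer_set()].
#' @param params A [band_shape_params()].
#' @return A data frame of class `simulated_spectrum` with columns
#'   `wavelength` (nm, increasing) and `delta_epsilon` (L mol^-1 cm^-1).
#' @export
simulate_ecd <- function(conformers, params = band_shape_params()) {
  conformers <- conformer_set(as.data.frame(conformers))
  stopifnot(inherits(params, "band_shape_params"))
  wl <- seq(params$grid_min, params$grid_max, by = params$grid_step)
  energies <- EV_NM / wl
  ids <- unique(conformers$conformer_id)
  rel <- vapply(ids, function(id)
    conformers$relative_energy_kcal[conformers$conformer_id == id][1],
    numeric(1))
  w <- boltzmann_weights(rel, params$temperature)
  pref <- 1 / (DELTA_EPS_CONST * sqrt(pi) * params$sigma)
  de <- numeric(length(wl))
  for (k in seq_along(ids)) {
    tr <- conformers[conformers$conformer_id == ids[k], ]
    gauss <- exp(-(outer(energies, tr$energy_ev, "-") / params$sigma)^2)
    contrib <- as.vector(gauss %*%
                           (tr$energy_ev * tr$rotational_strength_1e40cgs *
                              1e-40))
    de <- de + w[k] * pref * contrib
  }
  out <- data.frame(wavelength = wl, delta_epsilon = de)
  class(out) <- c("simulated_spectrum", "data.frame")
  out
}

#' Write / read a simulated spectrum (two-column CSV)
#' @param spectrum A `simulated_spectrum`.
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum)[, c("wavelength",
                                               "delta_epsilon")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("wavelength", "delta_epsilon"))
    if (!col %in% names(out)) stop("missing column: ", col)
  class(out) <- c("simulated_spectrum", "data.frame")
  out
}

#' Assign absolute configuration from a Cotton-effect sign
#'
#' Compares the experimental sign of the ECD band at a chosen wavelength
#' against the simulated spectrum of the R enantiomer: if the signs match,
#' the observed species is R, otherwise S. The call requires the simulated
#' spectrum to be significantly nonzero at that wavelength; near a node,
#' the assignment is refused and another wavelength must be chosen.
#'
#' @param experimental_sign `"positive"` or `"negative"` — the sign of the
#'   observed Cotton effect.
#' @param at_wavelength Wavelength in nm, inside the simulated grid.
#' @param simulated_R Simulated spectrum of the R enantiomer
#'   ([simulate_ecd()] output).
#' @param significance_floor Minimum |delta_epsilon| of the simulated
#'   spectrum at the wavelength (default 0.01 L mol^-1 cm^-1).
#' @return A list: `configuration` (`"R"` or `"S"`), `delta_epsilon_sim`
#'   (simulated value at the wavelength), `note` (confidence remark).
#' @export
assign_configuration <- function(experimental_sign = c("positive",
                                                       "negative"),
                                 at_wavelength, simulated_R,
                                 significance_floor = 0.01) {
  experimental_sign <- match.arg(experimental_sign)
  stopifnot(inherits(simulated_R, "simulated_spectrum"))
  wl <- simulated_R$wavelength
  if (at_wavelength < min(wl) || at_wavelength > max(wl))
    stop("wavelength outside the simulated grid")
  de_sim <- stats::approx(wl, simulated_R$delta_epsilon,
                          xout = at_wavelength)$y
  if (abs(de_sim) < significance_floor)
    stop("indeterminate assignment: simulated delta_epsilon = ",
         format(de_sim, digits = 3), " at ", at_wavelength,
         " nm is below the significance floor; pick another wavelength")
  sim_sign <- if (de_sim > 0) "positive" else "negative"
  configuration <- if (experimental_sign == sim_sign) "R" else "S"
  list(configuration = configuration, delta_epsilon_sim = de_sim,
       note = sprintf(
         "simulated R spectrum is %s at %g nm (|delta_eps| = %.3g); %s Cotton effect observed -> %s",
         sim_sign, at_wavelength, abs(de_sim), experimental_sign,
         configuration))
}
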