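#' Kuhn dissymmetry g-factor from integrated peak areas
#'
#' The g-factor is the ratio of the circular-dichroic absorbance difference
#' to the ordinary absorbance, `g = dA / A`. Here both are peak areas from
#' the dual-channel detector: the ECD channel reports ellipticity in mdeg
#' (`dA = theta / 32980`) and the UV channel absorbance in mAU
#' (`A = mAU / 1000`). Because both areas scale with the amount injected,
#' g is independent of concentration and pathlength for a fixed enantiomer
#' composition — the property that lets a single achiral-column injection
#' yield the enantiomeric excess.
#'
#' @param uv_area UV peak area, mAU·min (> 0).
#' @param ecd_area Signed ECD peak area, mdeg·min.
#' @param wavelength Detection wavelength, nm.
#' @param ellipticity_to_dA Ellipticity per unit dA, mdeg (default 32980,
#'   the standard CD conversion theta[mdeg] = 32980·dA).
#' @param mau_to_A mAU per absorbance unit (default 1000).
#' @return A list of class `g_factor` with `value` (dimensionless, dA/A
#'   scale), `wavelength`, `uv_area_used`, `ecd_area_used`.
#' @export
compute_g_factor <- function(uv_area, ecd_area, wavelength = 250,
                             ellipticity_to_dA = 32980, mau_to_A = 1000) {
  if (!is.finite(uv_area) || uv_area <= 0)
    stop("degenerate input: uv_area must be positive (no analyte)")
  value <- (ecd_area / ellipticity_to_dA) / (uv_area / mau_to_A)
  structure(list(value = value, wavelength = wavelength,
                 uv_area_used = uv_area, ecd_area_used = ecd_area),
            class = "g_factor")
}

#' @export
print.g_factor <- function(x, ...) {
  cat(sprintf("<g_factor> g = %.6g at %g nm (UV %.4g mAU.min, ECD %.4g mdeg.min)\n",
              x$value, x$wavelength, x$uv_area_used, x$ecd_area_used))
  invisible(x)
}

#' Enantiomeric excess from the g-factor ratio
#'
#' With ECD response proportional to the signed concentration difference
#' `c_R - c_S` and UV response proportional to the total `c_R + c_S`, the
#' concentration cancels in the ratio and `g_mix = ee * g_pure`. The signed
#' ee is therefore `g_mix / g_pure_ref`, with positive values meaning excess
#' of the reference enantiomer.
#'
#' @param g_mix `g_factor` of the mixture's product peak.
#' @param g_pure_ref `g_factor` of the pure reference enantiomer, measured
#'   at the same wavelength; must be nonzero.
#' @param ref_config Configuration of the reference enantiomer, `"R"` or
#'   `"S"`.
#' @param racemic_floor Below this |ee| the sample is called racemic
#'   (default 0.005, i.e. 0.5 % ee — under plausible detector precision).
#' @return A list of class `ee_estimate`: `ee` (signed fraction),
#'   `ee_percent` (100·|ee|, clipped to [0, 100]), `dominant` (`"R"`,
#'   `"S"` or `"racemic"`), `g_mix`, `g_pure_ref`.
#' @export
estimate_ee <- function(g_mix, g_pure_ref, ref_config = c("R", "S"),
                        racemic_floor = 0.005) {
  ref_config <- match.arg(ref_config)
  stopifnot(inherits(g_mix, "g_factor"), inherits(g_pure_ref, "g_factor"))
  if (g_mix$wavelength != g_pure_ref$wavelength)
    stop("wavelength mismatch between mixture and reference g-factors")
  if (!is.finite(g_pure_ref$value) || g_pure_ref$value == 0)
    stop("reference g-factor must be nonzero")
  ee <- g_mix$value / g_pure_ref$value
  if (abs(ee) > 1.05)
    stop("inconsistent reference: |ee| = ", format(abs(ee), digits = 4),
         " exceeds 1.05")
  if (abs(ee) > 1) {
    warning("|ee| slightly above 1 (", format(abs(ee), digits = 4),
            "); clipping to 1")
    ee <- sign(ee)
  }
  other <- if (ref_config == "R") "S" else "R"
  dominant <- if (ee > racemic_floor) ref_config
              else if (ee < -racemic_floor) other
              else "racemic"
  structure(list(ee = ee, ee_percent = min(100, 100 * abs(ee)),
                 dominant = dominant, g_mix = g_mix$value,
                 g_pure_ref = g_pure_ref$value),
            class = "ee_estimate")
}

#' @export
print.ee_estimate <- function(x, ...) {
  cat(sprintf("<ee_estimate> ee = %+.4f (%.2f%% %s)\n",
              x$ee, x$ee_percent, x$dominant))
  invisible(x)
}

#' Conversion ratio from substrate and product peak areas
#'
#' Area-percent conversion at the detection wavelength, with an optional
#' product-to-substrate UV response factor correcting for unequal molar
#' absorptivities:
#' `CR = 100 * (product/rf) / (product/rf + substrate)`.
#'
#' @param substrate_area Substrate UV peak area, mAU·min (>= 0).
#' @param product_area Product UV peak area, mAU·min (>= 0).
#' @param response_factor Product/substrate UV response ratio (default 1).
#' @return A list of class `conversion_result` with `cr` (percent, in
#'   [0, 100]), the two areas and the response factor used.
#' @export
conversion_ratio <- function(substrate_area, product_area,
                             response_factor = 1) {
  stopifnot(substrate_area >= 0, product_area >= 0, response_factor > 0)
  if (substrate_area == 0 && product_area == 0)
    stop("degenerate input: both peak areas are zero")
  prod_c <- product_area / response_factor
  structure(list(cr = 100 * prod_c / (prod_c + substrate_area),
                 substrate_area = substrate_area,
                 product_area = product_area,
                 response_factor = response_factor),
            class = "conversion_result")
}

#' Ordinary least-squares calibration line
#'
#' Fits `y = intercept + slope * x` for a standard curve (e.g. detector
#' response vs concentration, or summed ECD area vs R content).
#'
#' @param x Predictor (fractions or concentrations), length >= 3, not all
#'   equal.
#' @param y Responses, same length.
#' @return A list of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared` (NA with `r_squared_defined = FALSE` when y has zero
#'   variance), `n`, `residual_sd`.
#' @export
fit_calibration <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("calibration needs at least 3 points")
  if (diff(range(x)) == 0) stop("degenerate x: all values equal")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  defined <- ss_tot > 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (defined) 1 - ss_res / ss_tot else NA_real_,
                 r_squared_defined = defined,
                 n = length(x),
                 residual_sd = stats::sigma(fit),
                 x = x, y = y),
            class = "calibration_fit")
}

#' Check a calibration fit against the method's linearity requirements
#'
#' Two validation modes mirror the method's standard-curve behaviour over
#' mixtures of pure enantiomers at fixed total concentration: the UV area
#' must stay constant across R content (`"uv-constant"`) while the summed
#' ECD area must be linear in R content (`"ecd-linear"`).
#'
#' @param fit A [fit_calibration()] result.
#' @param mode `"uv-constant"` or `"ecd-linear"`.
#' @param slope_tolerance For `uv-constant`: maximum allowed relative change
#'   of the fitted line over the x span, `|slope|*span(x) <
#'   slope_tolerance*mean(y)` (default 0.05).
#' @param r2_min For `ecd-linear`: minimum r-squared (default 0.99).
#' @return A list with `pass` (logical), `mode`, and a one-line `report`.
#' @export
check_linearity <- function(fit, mode = c("uv-constant", "ecd-linear"),
                            slope_tolerance = 0.05, r2_min = 0.99) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "calibration_fit"))
  if (mode == "uv-constant") {
    span <- diff(range(fit$x))
    drift <- abs(fit$slope) * span
    lim <- slope_tolerance * abs(mean(fit$y))
    pass <- drift < lim
    report <- sprintf(
      "uv-constant: |slope|*span = %.4g vs %.4g (%.0f%% of mean) -> %s",
      drift, lim, 100 * slope_tolerance, if (pass) "PASS" else "FAIL")
  } else {
    pass <- fit$r_squared_defined && fit$r_squared >= r2_min
    report <- sprintf("ecd-linear: r^2 = %s (min %.3g) -> %s",
                      if (fit$r_squared_defined)
                        format(fit$r_squared, digits = 6) else "undefined",
                      r2_min, if (pass) "PASS" else "FAIL")
  }
  list(pass = pass, mode = mode, report = report)
}

#' Concentration invariance of the g-factor
#'
#' For a pure enantiomer the g-factor must not depend on the amount
#' injected. Given g-factors measured across a concentration series, this
#' returns the coefficient of variation `CV = sd_pop / |mean|` (population
#' standard deviation) and a pass verdict against a threshold.
#'
#' @param g_values Numeric vector of g-factor values (or a list of
#'   `g_factor` objects), length >= 3, from one pure enantiomer.
#' @param cv_threshold Maximum acceptable CV (default 0.05).
#' @return A list with `cv`, `mean_g`, `n`, `pass`.
#' @export
g_concentration_invariance <- function(g_values, cv_threshold = 0.05) {
  if (is.list(g_values))
    g_values <- vapply(g_values, function(g) g$value, numeric(1))
  if (length(g_values) < 3)
    stop("need at least 3 concentration levels")
  m <- mean(g_values)
  sd_pop <- sqrt(mean((g_values - m)^2))
  if (m == 0 || sd_pop > 1e6 * abs(m))
    stop("undefined CV: mean g is zero or indistinguishable from zero ",
         "(racemic input?)")
  cv <- sd_pop / abs(m)
  list(cv = cv, mean_g = m, n = length(g_values), pass = cv <= cv_threshold)
}
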