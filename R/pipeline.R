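#' Pipeline configuration
#'
#' Bundles every tunable of the single-injection analysis: detection
#' wavelength, unit constants, peak finding, retention-time windows used to
#' assign detected peaks to species, the reference g-factor of the pure
#' reference enantiomer, and the racemic call floor.
#'
#' @param wavelength Detection wavelength, nm.
#' @param ellipticity_to_dA,mau_to_A Unit constants (see
#'   [compute_g_factor()]).
#' @param peaks A [peak_params()] object.
#' @param rt_window_substrate,rt_window_product Two-element `c(min, max)`
#'   retention-time windows (minutes) for species assignment; within a
#'   window the peak with apex nearest the window centre is taken.
#' @param response_factor Product/substrate UV response factor for the
#'   conversion ratio.
#' @param g_pure_ref Reference g-factor value of the pure reference
#'   enantiomer (numeric, dA/A scale) or NULL when unknown — the ee is then
#'   omitted from reports.
#' @param ref_config Configuration of the reference enantiomer.
#' @param racemic_floor |ee| below which a sample is called racemic.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(wavelength = 250,
                            ellipticity_to_dA = 32980, mau_to_A = 1000,
                            peaks = peak_params(),
                            rt_window_substrate = c(3.0, 4.5),
                            rt_window_product = c(5.0, 7.5),
                            response_factor = 1,
                            g_pure_ref = NULL,
                            ref_config = c("R", "S"),
                            racemic_floor = 0.005) {
  ref_config <- match.arg(ref_config)
  stopifnot(wavelength > 0, length(rt_window_substrate) == 2,
            length(rt_window_product) == 2, response_factor > 0)
  structure(list(wavelength = wavelength,
                 ellipticity_to_dA = ellipticity_to_dA,
                 mau_to_A = mau_to_A, peaks = peaks,
                 rt_window_substrate = rt_window_substrate,
                 rt_window_product = rt_window_product,
                 response_factor = response_factor,
                 g_pure_ref = g_pure_ref, ref_config = ref_config,
                 racemic_floor = racemic_floor),
            class = "pipeline_config")
}

# nearest apex to the window centre, among peaks whose apex lies inside
match_peak <- function(peaks, window) {
  inside <- peaks$rt >= window[1] & peaks$rt <= window[2]
  if (!any(inside)) return(NULL)
  cand <- peaks[inside, , drop = FALSE]
  cand[which.min(abs(cand$rt - mean(window))), , drop = FALSE]
}

#' Analyse one achiral-column injection
#'
#' The single-injection workflow: detect peaks, assign the substrate and
#' product peaks by retention-time window, compute the conversion ratio
#' from UV areas, the product g-factor from the paired UV/ECD areas, and —
#' when a pure-enantiomer reference g is configured — the signed ee and
#' dominant configuration.
#'
#' @param chrom A `chromatogram` (achiral column: the two enantiomers
#'   co-elute in the product peak).
#' @param config A [pipeline_config()].
#' @param sample_id Label carried into the report (defaults to the
#'   chromatogram's `meta$sample_id`, if any).
#' @return A list of class `injection_report`: `sample_id`, `cr`,
#'   `ee`, `ee_percent`, `dominant`, `g_mix`, `g_pure_ref`, `wavelength`
#'   (ee fields NA when no reference g is configured), plus `peaks` (the
#'   full peak table) for traceability.
#' @export
analyze_injection <- function(chrom, config = pipeline_config(),
                              sample_id = NULL) {
  validate_chromatogram(chrom)
  if (is.null(sample_id))
    sample_id <- if (!is.null(chrom$meta$sample_id))
      chrom$meta$sample_id else "sample"
  peaks <- detect_peaks(chrom, config$peaks)
  if (!nrow(peaks)) stop("no peaks detected")
  substrate <- match_peak(peaks, config$rt_window_substrate)
  product <- match_peak(peaks, config$rt_window_product)
  if (is.null(product))
    stop("no product peak found in window [",
         paste(config$rt_window_product, collapse = ", "), "] min")
  substrate_area <- if (is.null(substrate)) 0 else substrate$uv_area
  cr <- conversion_ratio(substrate_area, product$uv_area,
                         config$response_factor)$cr
  g_mix <- compute_g_factor(product$uv_area, product$ecd_area,
                            wavelength = config$wavelength,
                            ellipticity_to_dA = config$ellipticity_to_dA,
                            mau_to_A = config$mau_to_A)
  ee <- ee_percent <- NA_real_; dominant <- NA_character_
  g_ref <- NA_real_
  if (!is.null(config$g_pure_ref)) {
    ref <- structure(list(value = config$g_pure_ref,
                          wavelength = config$wavelength,
                          uv_area_used = Inf, ecd_area_used = NA_real_),
                     class = "g_factor")
    est <- estimate_ee(g_mix, ref, ref_config = config$ref_config,
                       racemic_floor = config$racemic_floor)
    ee <- est$ee; ee_percent <- est$ee_percent; dominant <- est$dominant
    g_ref <- config$g_pure_ref
  }
  structure(list(sample_id = sample_id, cr = cr, ee = ee,
                 ee_percent = ee_percent, dominant = dominant,
                 g_mix = g_mix$value, g_pure_ref = g_ref,
                 wavelength = config$wavelength, peaks = peaks),
            class = "injection_report")
}

#' @export
print.injection_report <- function(x, ...) {
  cat(sprintf("<injection_report> %s: CR %.2f%%", x$sample_id, x$cr))
  if (!is.na(x$ee))
    cat(sprintf(", ee %.2f%% (%s), g = %.4g", x$ee_percent, x$dominant,
                x$g_mix))
  cat("\n")
  invisible(x)
}

#' Analyse a batch of injections
#'
#' @param chroms List of chromatograms (or paths to chromatogram CSVs).
#' @param config A [pipeline_config()].
#' @return A data frame with one row per injection: `sample_id`, `cr`,
#'   `ee`, `ee_percent`, `dominant`, `g_mix`, `g_pure_ref`, `wavelength`.
#' @export
batch_analyze <- function(chroms, config = pipeline_config()) {
  reports <- lapply(chroms, function(ch) {
    if (is.character(ch)) ch <- read_chromatogram(ch)
    analyze_injection(ch, config)
  })
  do.call(rbind, lapply(reports, function(r)
    data.frame(sample_id = r$sample_id, cr = r$cr, ee = r$ee,
               ee_percent = r$ee_percent, dominant = r$dominant,
               g_mix = r$g_mix, g_pure_ref = r$g_pure_ref,
               wavelength = r$wavelength)))
}

#' Write injection reports to JSON and/or CSV
#'
#' The JSON holds one record per injection with the fields `sample_id`,
#' `cr`, `ee_percent`, `dominant`, `g_mix`, `g_pure_ref`, `wavelength`;
#' the CSV carries identical columns. Output is deterministic for
#' identical inputs (no timestamps).
#'
#' @param reports A data frame from [batch_analyze()] or a single
#'   `injection_report`.
#' @param json_path,csv_path Output paths (NULL to skip either).
#' @return The report data frame, invisibly.
#' @export
write_injection_report <- function(reports, json_path = NULL,
                                   csv_path = NULL) {
  if (inherits(reports, "injection_report"))
    reports <- batch_to_df(reports)
  cols <- c("sample_id", "cr", "ee_percent", "dominant", "g_mix",
            "g_pure_ref", "wavelength")
  df <- reports[, cols]
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

batch_to_df <- function(r) {
  data.frame(sample_id = r$sample_id, cr = r$cr, ee = r$ee,
             ee_percent = r$ee_percent, dominant = r$dominant,
             g_mix = r$g_mix, g_pure_ref = r$g_pure_ref,
             wavelength = r$wavelength)
}

#' Range-analyse every response of an orthogonal-array experiment
#'
#' Runs [range_analysis()] and [predict_optimal_conditions()] for each
#' response column and assembles a combined report table in the classical
#' layout (level means M1–M3, ranges R, factor order, optimal levels and
#' combination, side by side per response).
#'
#' @param responses Response table aligned with `design`.
#' @param design An `orthogonal_design` (default [build_L9()]).
#' @param response_names Response columns to analyse (default every
#'   non-factor, non-run column).
#' @return A list of class `optimization_report`: per response the
#'   `range_analysis` result and optimal-condition prediction, plus
#'   `table` — the combined display data frame (values rounded half-up to
#'   2 decimals).
#' @export
optimize_responses <- function(responses, design = build_L9(),
                               response_names = NULL) {
  responses <- validate_response_table(responses, design)
  if (is.null(response_names))
    response_names <- setdiff(names(responses),
                              c("run", design$factor_names))
  analyses <- lapply(response_names, function(rn)
    range_analysis(design, responses, rn))
  names(analyses) <- response_names
  predictions <- lapply(analyses, predict_optimal_conditions,
                        design = design)
  blocks <- lapply(response_names, function(rn) {
    a <- analyses[[rn]]
    blk <- rbind(round_half_up(a$M, 2), R = round_half_up(a$R, 2))
    colnames(blk) <- paste(rn, colnames(blk), sep = ".")
    blk
  })
  tab <- as.data.frame(do.call(cbind, blocks))
  footer <- lapply(response_names, function(rn) list(
    factor_order = paste(analyses[[rn]]$factor_order, collapse = " > "),
    optimal_combination = analyses[[rn]]$optimal_combination,
    present_in_runs = predictions[[rn]]$present_in_runs))
  names(footer) <- response_names
  structure(list(analyses = analyses, predictions = predictions,
                 table = tab, footer = footer),
            class = "optimization_report")
}

#' @export
print.optimization_report <- function(x, ...) {
  print(x$table)
  for (rn in names(x$footer)) {
    f <- x$footer[[rn]]
    cat(sprintf("%s: factor order %s; optimal %s (%s among the runs)\n",
                rn, f$factor_order, f$optimal_combination,
                if (f$present_in_runs) "present" else "absent"))
  }
  invisible(x)
}

#' Write an optimization report to JSON
#'
#' Exports per response the full-precision M matrix, R vector, factor
#' order, optimal combination and physical optimal settings.
#'
#' @param report An `optimization_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_optimization_report <- function(report, path) {
  out <- lapply(names(report$analyses), function(rn) {
    a <- report$analyses[[rn]]
    p <- report$predictions[[rn]]
    list(response = rn,
         M = apply(a$M, 2, identity, simplify = FALSE),
         R = as.list(a$R),
         factor_order = a$factor_order,
         optimal_combination = a$optimal_combination,
         optimal_settings = p$settings,
         present_in_runs = p$present_in_runs)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
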