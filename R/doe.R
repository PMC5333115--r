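#' Build the standard L9(3^4) orthogonal array
#'
#' Nine runs accommodating up to four 3-level factors such that in every
#' column each level appears exactly three times and every ordered level
#' pair across any two columns appears exactly once. Three columns carry
#' the reaction factors here — catalyst loading (A, mol %), temperature
#' (B, deg C) and reaction time (C, h); the fourth column is retained
#' internally as the unassigned (error) column and excluded from reports.
#'
#' @param factor_names Labels for the assigned columns (default A, B, C).
#' @param level_values Named list mapping each factor to its three physical
#'   level values. Defaults are the hydrosilylation screening levels:
#'   A = 5/10/20 mol %, B = -10/0/10 deg C, C = 8/16/24 h.
#' @return A list of class `orthogonal_design` with `array` (9 x 4 integer
#'   matrix of levels), `factor_names`, `level_values`, `level_units`.
#' @export
build_L9 <- function(factor_names = c("A", "B", "C"),
                     level_values = list(A = c(5, 10, 20),
                                         B = c(-10, 0, 10),
                                         C = c(8, 16, 24))) {
  stopifnot(length(factor_names) <= 3,
            setequal(names(level_values), factor_names),
            all(vapply(level_values, length, 1L) == 3))
  arr <- matrix(c(1, 1, 1, 1,
                  1, 2, 2, 2,
                  1, 3, 3, 3,
                  2, 1, 2, 3,
                  2, 2, 3, 1,
                  2, 3, 1, 2,
                  3, 1, 3, 2,
                  3, 2, 1, 3,
                  3, 3, 2, 1),
                nrow = 9, byrow = TRUE)
  colnames(arr) <- c(factor_names,
                     rep("unused", 4 - length(factor_names)))
  structure(list(array = arr, factor_names = factor_names,
                 level_values = level_values,
                 level_units = c(A = "mol %", B = "deg C", C = "h")),
            class = "orthogonal_design")
}

#' Check the orthogonality of a design
#'
#' @param design An `orthogonal_design`.
#' @return TRUE if each column is balanced (each level 3 times) and every
#'   column pair contains each ordered level pair exactly once; otherwise
#'   an error describing the violation.
#' @export
check_orthogonality <- function(design) {
  arr <- design$array
  for (j in seq_len(ncol(arr))) {
    tab <- tabulate(arr[, j], 3)
    if (!all(tab == 3))
      stop("column ", j, " is unbalanced: ", paste(tab, collapse = "/"))
  }
  for (j in seq_len(ncol(arr) - 1)) for (k in (j + 1):ncol(arr)) {
    pairs <- paste(arr[, j], arr[, k])
    if (any(table(pairs) != 1) || length(unique(pairs)) != 9)
      stop("columns ", j, " and ", k, " are not orthogonal")
  }
  TRUE
}

#' Read an orthogonal-array response table (CSV)
#'
#' Expects columns `run`, one column per design factor (levels 1..3) and
#' one column per response (e.g. `cr`, `op`).
#'
#' @param path File path.
#' @param design The `orthogonal_design` the rows must align with.
#' @return A data frame with 9 rows, checked against the design.
#' @export
read_response_table <- function(path, design = build_L9()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_response_table(df, design)
}

#' @rdname read_response_table
#' @param responses Response data frame to validate.
#' @export
validate_response_table <- function(responses, design = build_L9()) {
  arr <- design$array
  if (nrow(responses) != nrow(arr))
    stop("response table must have ", nrow(arr), " rows")
  if ("run" %in% names(responses))
    responses <- responses[order(responses$run), , drop = FALSE]
  for (f in design$factor_names) {
    if (!f %in% names(responses)) stop("missing factor column: ", f)
    if (!all(responses[[f]] == arr[, f]))
      stop("levels in column ", f, " do not match the design")
  }
  rownames(responses) <- NULL
  responses
}

#' Taguchi range analysis of one response over an orthogonal array
#'
#' For each factor and level, the level mean M is the average of the
#' response over the runs where the factor sits at that level; the range R
#' is `max(M) - min(M)` per factor, computed from unrounded means. Factors
#' are ranked by descending R (ties keep declaration order) and the optimal
#' level per factor is the one with the largest M (larger response assumed
#' better; ties pick the lowest level). All arithmetic is full precision;
#' rounding is applied only for display.
#'
#' @param design An `orthogonal_design`.
#' @param responses Response table aligned with the design (see
#'   [validate_response_table()]).
#' @param response_name Name of the response column to analyse.
#' @return A list of class `range_analysis`: `M` (3 x n_factor matrix of
#'   level means), `R` (named range vector), `factor_order`,
#'   `optimal_level` (named integer), `optimal_combination` (e.g.
#'   `"A2B3C3"`), `grand_mean`, `ties` (logical flags `R` and `M`),
#'   `response_name`.
#' @export
range_analysis <- function(design, responses, response_name) {
  responses <- validate_response_table(responses, design)
  if (!response_name %in% names(responses))
    stop("missing response column: ", response_name)
  y <- responses[[response_name]]
  if (!all(is.finite(y))) stop("responses must be finite")
  fac <- design$factor_names
  M <- matrix(NA_real_, nrow = 3, ncol = length(fac),
              dimnames = list(paste0("M", 1:3), fac))
  for (f in fac) for (l in 1:3)
    M[l, f] <- mean(y[design$array[, f] == l])
  R <- apply(M, 2, max) - apply(M, 2, min)
  # stable sort: ties keep factor declaration order
  factor_order <- fac[order(-R[fac])]
  tie_R <- anyDuplicated(signif(R, 12)) > 0
  optimal_level <- vapply(fac, function(f) which.max(M[, f]), integer(1))
  tie_M <- any(vapply(fac, function(f)
    sum(M[, f] == max(M[, f])) > 1, logical(1)))
  structure(list(
    M = M, R = R, factor_order = factor_order,
    optimal_level = optimal_level,
    optimal_combination = paste0(fac, optimal_level, collapse = ""),
    grand_mean = mean(y),
    ties = list(R = tie_R, M = tie_M),
    response_name = response_name),
    class = "range_analysis")
}

#' @export
print.range_analysis <- function(x, digits = 2, ...) {
  cat(sprintf("Range analysis of '%s'\n", x$response_name))
  print(round_half_up(x$M, digits))
  cat("R: ", paste(sprintf("%s=%s", names(x$R),
                           format(round_half_up(x$R, digits), nsmall = digits)),
                   collapse = "  "), "\n")
  cat("Factor order:", paste(x$factor_order, collapse = " > "), "\n")
  cat("Optimal combination:", x$optimal_combination,
      if (x$ties$R || x$ties$M) "(ties present)" else "", "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (0.005 -> 0.01), the
#' convention used for reporting level means and ranges; base `round()`
#' rounds half to even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric of the same shape.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Map optimal levels to physical settings
#'
#' Translates a range-analysis optimum into physical factor values and
#' reports whether that level combination was actually executed among the
#' design's runs (the best predicted combination need not be).
#'
#' @param result A [range_analysis()] result.
#' @param design The `orthogonal_design` analysed.
#' @return A list: `settings` (named list of physical values),
#'   `combination` label, `present_in_runs` (logical), `run_no` (matching
#'   run number or NA).
#' @export
predict_optimal_conditions <- function(result, design) {
  stopifnot(inherits(result, "range_analysis"))
  fac <- design$factor_names
  lev <- result$optimal_level[fac]
  settings <- stats::setNames(
    lapply(fac, function(f) design$level_values[[f]][lev[f]]), fac)
  runs <- design$array[, fac, drop = FALSE]
  hit <- which(apply(runs, 1, function(r) all(r == lev)))
  list(settings = settings,
       combination = result$optimal_combination,
       present_in_runs = length(hit) > 0,
       run_no = if (length(hit)) hit[1] else NA_integer_)
}

#' Packaged orthogonal-array screening results for the hydrosilylation
#'
#' Loads the packaged 9-run response table for the asymmetric
#' hydrosilylation screening (conversion ratio `cr` and optical purity
#' `op`, both %), aligned with [build_L9()]. These responses are
#' instrument-derived inputs, shipped as a fixture; they are not
#' computable from first principles.
#'
#' @return A 9-row data frame with columns `run`, `A`, `B`, `C`, `cr`,
#'   `op`.
#' @export
hydrosilylation_responses <- function() {
  path <- system.file("extdata", "hydrosilylation_l9_responses.csv",
                      package = "chiroptic", mustWork = TRUE)
  read_response_table(path)
}
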