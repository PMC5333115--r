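#' Construct a dual-channel chromatogram
#'
#' A chromatogram holds the two time-aligned channels of an HPLC run with a
#' dual UV/ECD detector: ordinary absorbance (mAU) and ellipticity (mdeg),
#' sampled on one uniform time grid at a single detection wavelength.
#'
#' @param time Numeric vector of acquisition times in minutes; strictly
#'   increasing, uniform grid (relative step deviation below 1e-6).
#' @param uv UV absorbance trace in mAU, same length as `time`.
#' @param ecd Ellipticity trace in mdeg, same length as `time`.
#' @param wavelength Detection wavelength in nm (default 250).
#' @param meta Named list of free-form metadata (e.g. `column`, `sample_id`).
#'
#' @return An object of class `chromatogram`: a list with elements `time`,
#'   `uv`, `ecd`, `wavelength`, `meta`.
#' @export
chromatogram <- function(time, uv, ecd, wavelength = 250, meta = list()) {
  time <- as.numeric(time); uv <- as.numeric(uv); ecd <- as.numeric(ecd)
  obj <- structure(
    list(time = time, uv = uv, ecd = ecd,
         wavelength = as.numeric(wavelength), meta = meta),
    class = "chromatogram"
  )
  validate_chromatogram(obj)
}

#' Validate a chromatogram object
#'
#' Checks the invariants: equal channel lengths (>= 2), a strictly
#' increasing uniform time grid, and a positive detection wavelength.
#'
#' @param x A `chromatogram`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_chromatogram <- function(x) {
  if (!inherits(x, "chromatogram")) stop("not a chromatogram object")
  n <- length(x$time)
  if (n < 2L) stop("chromatogram must have at least 2 points")
  if (length(x$uv) != n || length(x$ecd) != n)
    stop("time, uv and ecd must have equal length")
  if (anyNA(x$time) || anyNA(x$uv) || anyNA(x$ecd))
    stop("chromatogram channels must not contain NA")
  dt <- diff(x$time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - mean(dt))) / mean(dt) >= 1e-6)
    stop("time grid must be uniform (relative step deviation < 1e-6)")
  if (!is.finite(x$wavelength) || x$wavelength <= 0)
    stop("wavelength must be positive")
  x
}

#' Time step of a chromatogram grid (minutes)
#' @param chrom A `chromatogram`.
#' @return Scalar grid step in minutes.
#' @export
time_step <- function(chrom) mean(diff(chrom$time))

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d points, %.3f-%.3f min, %g nm\n",
              length(x$time), x$time[1], x$time[length(x$time)],
              x$wavelength))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Read a chromatogram from CSV
#'
#' The file dialect is plain UTF-8 CSV with columns `time`, `uv`, `ecd`
#' (decimal point `.`), optionally preceded by metadata header lines of the
#' form `#key=value`. The keys `wavelength` (numeric, nm) is promoted to the
#' chromatogram's wavelength; all other keys land in `meta`.
#'
#' @param path Path to the CSV file.
#' @param format File format; only `"csv"` is supported.
#' @return A validated [chromatogram()].
#' @export
read_chromatogram <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"),
                        stringsAsFactors = FALSE)
  for (col in c("time", "uv", "ecd"))
    if (!col %in% names(df)) stop("missing column: ", col)
  wl <- 250
  if (!is.null(meta$wavelength)) {
    wl <- as.numeric(meta$wavelength)
    meta$wavelength <- NULL
  }
  chromatogram(df$time, df$uv, df$ecd, wavelength = wl, meta = meta)
}

#' Write a chromatogram to CSV
#'
#' Emits `#key=value` metadata header lines (wavelength always included),
#' then `time,uv,ecd` columns at 9 significant digits, so that a
#' write/read round trip reproduces the traces to better than 1e-9
#' relative.
#'
#' @param chrom A `chromatogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  validate_chromatogram(chrom)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#wavelength=%s", format(chrom$wavelength, digits = 9)),
             con)
  for (k in names(chrom$meta))
    writeLines(sprintf("#%s=%s", k, as.character(chrom$meta[[k]])), con)
  writeLines("time,uv,ecd", con)
  writeLines(sprintf("%.9e,%.9e,%.9e", chrom$time, chrom$uv, chrom$ecd),
             con)
  invisible(path)
}

#' Peak-finding parameters
#'
#' @param min_height Minimum apex height above baseline, mAU (> 0).
#' @param min_prominence Minimum topographic prominence, mAU (> 0).
#' @param baseline_mode Baseline model: `"linear-endpoints"` (line through
#'   the window endpoints; default) or `"rolling-minimum"` (morphological
#'   opening — rolling minimum then rolling maximum — for drifting
#'   baselines).
#' @param smoothing_window Moving-average window in points (odd, >= 1) used
#'   only for apex localisation; areas are always integrated on raw data.
#' @param rolling_width Width in points of the rolling-minimum baseline
#'   window (used only when `baseline_mode = "rolling-minimum"`).
#' @param bound_frac Fraction of apex height at which the peak bounds are
#'   placed when no baseline crossing or valley intervenes.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(min_height = 1, min_prominence = 1,
                        baseline_mode = c("linear-endpoints",
                                          "rolling-minimum"),
                        smoothing_window = 1L, rolling_width = 101L,
                        bound_frac = 0.001) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(min_height > 0, min_prominence > 0,
            smoothing_window >= 1, smoothing_window %% 2 == 1,
            bound_frac > 0, bound_frac < 1)
  structure(list(min_height = min_height, min_prominence = min_prominence,
                 baseline_mode = baseline_mode,
                 smoothing_window = as.integer(smoothing_window),
                 rolling_width = as.integer(rolling_width),
                 bound_frac = bound_frac),
            class = "peak_params")
}

# centered moving average; shrinks the window at the edges
moving_average <- function(y, k) {
  if (k <= 1L) return(y)
  h <- (k - 1L) %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

rolling_extremum <- function(y, k, fun) {
  n <- length(y)
  h <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- fun(y[max(1L, i - h):min(n, i + h)])
  out
}

# morphological opening: a rolling minimum (which erases peaks narrower
# than the window) followed by a rolling maximum (which restores sloping
# baselines the erosion shifted)
rolling_min_baseline <- function(y, k) {
  rolling_extremum(rolling_extremum(y, k, min), k, max)
}

# baseline estimate for a whole trace under the given mode
trace_baseline <- function(y, mode, rolling_width = 101L) {
  if (mode == "linear-endpoints") {
    n <- length(y)
    y[1] + (y[n] - y[1]) * (seq_len(n) - 1) / (n - 1)
  } else {
    rolling_min_baseline(y, rolling_width)
  }
}

# topographic prominence of apex indices in y (already baseline-corrected)
peak_prominences <- function(y, apexes) {
  vapply(apexes, function(i) {
    h <- y[i]
    higher_left <- apexes[apexes < i & y[apexes] > h]
    lo <- if (length(higher_left)) max(higher_left) else 1L
    left_min <- min(y[lo:i])
    higher_right <- apexes[apexes > i & y[apexes] > h]
    hi <- if (length(higher_right)) min(higher_right) else length(y)
    right_min <- min(y[i:hi])
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect peaks in the UV channel and integrate both channels
#'
#' Apexes are local maxima of the (optionally smoothed) baseline-corrected
#' UV trace exceeding `min_height` and `min_prominence`. Each peak's bounds
#' are the nearest points, walking outward from the apex, where the smoothed
#' corrected signal falls to `bound_frac` of the apex height, meets the
#' valley shared with a neighbouring peak, or hits the grid edge. UV and signed ECD
#' areas are then trapezoid-integrated over the same bounds (the two
#' detector channels see the same eluate) after baseline subtraction,
#' always on the unsmoothed data.
#'
#' @param chrom A `chromatogram`.
#' @param params A [peak_params()] object.
#' @return A data frame of class `peak_table` with one row per peak, sorted
#'   by retention time: `rt`, `t_start`, `t_end`, `uv_height`, `uv_area`
#'   (mAU·min, >= 0), `ecd_area` (mdeg·min, signed).
#' @export
detect_peaks <- function(chrom, params = peak_params()) {
  validate_chromatogram(chrom)
  y_raw <- chrom$uv
  base <- trace_baseline(y_raw, params$baseline_mode, params$rolling_width)
  y <- y_raw - base
  ys <- moving_average(y, params$smoothing_window)
  n <- length(ys)

  empty <- data.frame(rt = numeric(0), t_start = numeric(0),
                      t_end = numeric(0), uv_height = numeric(0),
                      uv_area = numeric(0), ecd_area = numeric(0))
  class(empty) <- c("peak_table", "data.frame")

  inner <- 2:(n - 1)
  is_apex <- ys[inner] > ys[inner - 1] & ys[inner] >= ys[inner + 1]
  apexes <- inner[is_apex]
  apexes <- apexes[y[apexes] >= params$min_height]
  if (!length(apexes)) return(empty)
  prom <- peak_prominences(ys, apexes)
  keep <- prom >= params$min_prominence
  apexes <- apexes[keep]
  if (!length(apexes)) return(empty)

  rows <- lapply(seq_along(apexes), function(j) {
    i <- apexes[j]
    cut <- params$bound_frac * ys[i]
    # search region: up to the valley shared with the neighbouring peak,
    # or the grid edge; the bound is the point nearest the apex where the
    # smoothed corrected signal falls to the cut, else the valley itself
    left_lim <- if (j > 1) apexes[j - 1] else 1L
    seg <- left_lim:i
    valley <- seg[which.min(ys[seg])]
    below <- valley - 1L + which(ys[valley:i] <= cut)
    lo <- if (length(below)) max(below) else valley
    right_lim <- if (j < length(apexes)) apexes[j + 1] else n
    seg <- i:right_lim
    valley <- i - 1L + which.min(ys[seg])
    below <- i - 1L + which(ys[i:valley] <= cut)
    hi <- if (length(below)) min(below) else valley
    if (lo >= i) lo <- max(1L, i - 1L)
    if (hi <= i) hi <- min(n, i + 1L)
    areas <- integrate_window(chrom, chrom$time[lo], chrom$time[hi],
                              baseline_mode = params$baseline_mode,
                              rolling_width = params$rolling_width)
    data.frame(rt = chrom$time[i], t_start = chrom$time[lo],
               t_end = chrom$time[hi], uv_height = y[i],
               uv_area = max(areas[["uv_area"]], 0),
               ecd_area = areas[["ecd_area"]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Baseline-corrected trapezoid areas over a time window
#'
#' Integrates both channels over `[t_start, t_end]` by the trapezoid rule
#' on the raw grid after baseline subtraction. Under
#' `"linear-endpoints"` the baseline of each channel is the straight line
#' through that channel's values at the window endpoints; under
#' `"rolling-minimum"` it is the morphological opening of the full trace
#' (rolling minimum then rolling maximum) evaluated inside the window.
#' The ECD area keeps its sign.
#'
#' @param chrom A `chromatogram`.
#' @param t_start,t_end Window bounds in minutes, inside the time grid.
#' @param baseline_mode `"linear-endpoints"` or `"rolling-minimum"`.
#' @param rolling_width Points in the rolling-minimum window.
#' @return Named numeric vector `c(uv_area = , ecd_area = )` in
#'   signal·min.
#' @export
integrate_window <- function(chrom, t_start, t_end,
                             baseline_mode = c("linear-endpoints",
                                               "rolling-minimum"),
                             rolling_width = 101L) {
  validate_chromatogram(chrom)
  baseline_mode <- match.arg(baseline_mode)
  if (t_start >= t_end) stop("t_start must be < t_end")
  tmin <- chrom$time[1]; tmax <- chrom$time[length(chrom$time)]
  eps <- 1e-9 * (tmax - tmin)
  if (t_start < tmin - eps || t_end > tmax + eps)
    stop("integration window outside the time grid")
  idx <- which(chrom$time >= t_start - eps & chrom$time <= t_end + eps)
  if (length(idx) < 2) stop("integration window spans fewer than 2 points")
  tt <- chrom$time[idx]
  one <- function(y) {
    yw <- y[idx]
    bl <- if (baseline_mode == "linear-endpoints") {
      yw[1] + (yw[length(yw)] - yw[1]) * (tt - tt[1]) / (tt[length(tt)] - tt[1])
    } else {
      rolling_min_baseline(y, rolling_width)[idx]
    }
    pracma::trapz(tt, yw - bl)
  }
  c(uv_area = one(chrom$uv), ecd_area = one(chrom$ecd))
}
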