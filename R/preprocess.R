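#' Spectrum matrix
#'
#' An n pixels x p bands matrix of spectra bound to a [wavelength_grid()],
#' with optional per-row class labels (0 = clean, 1 = contaminated). This is
#' the working container for preprocessing and sparse PCA.
#'
#' @param values Numeric n x p matrix.
#' @param grid A [wavelength_grid()] with p centers.
#' @param labels Optional integer vector of per-row class codes in \{0, 1\}.
#' @return An object of class `spectrum_matrix`.
#' @export
spectrum_matrix <- function(values, grid, labels = NULL) {
  values <- as.matrix(values)
  grid <- if (inherits(grid, "wavelength_grid")) grid else wavelength_grid(grid)
  if (ncol(values) != length(grid)) {
    stop(sprintf("spectrum matrix has %d bands but grid has %d",
                 ncol(values), length(grid)))
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values)) stop("labels length must equal row count")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 (clean) or 1 (contaminated)")
  }
  structure(list(values = values, grid = grid, labels = labels),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %d spectra x %d bands (%.1f-%.1f nm)%s\n",
              nrow(x$values), ncol(x$values), min(x$grid), max(x$grid),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Flatten a cube to a spectrum matrix
#'
#' Pixels are unrolled row-major (row 1 left to right, then row 2, ...), so
#' row `(r - 1) * cols + c` of the matrix is pixel `(r, c)`.
#'
#' @param cube An [hs_cube()].
#' @return A [spectrum_matrix()] with `rows * cols` rows.
#' @export
cube_to_spectra <- function(cube) {
  d <- dim(cube$data)
  m <- matrix(aperm(cube$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  spectrum_matrix(m, cube$grid)
}

# ---- Step 1: laser band removal ---------------------------------------------

#' Remove laser-contaminated short-wavelength bands
#'
#' Bands below the excitation cutoff are dominated by laser scatter and
#' Rayleigh scattering rather than fluorescence and are dropped. The rule is
#' half-open: centers `< cutoff_nm` are removed, a center exactly at the
#' cutoff is kept. On the uniform 128-band 400--1000 nm grid with the
#' default 480 nm cutoff this removes 17 bands and retains 111.
#'
#' @param m A [spectrum_matrix()].
#' @param cutoff_nm Cutoff wavelength in nm (default 480, just above the
#'   450 nm excitation line).
#' @return A [spectrum_matrix()] on the truncated grid.
#' @export
remove_laser_bands <- function(m, cutoff_nm = 480) {
  keep <- as.numeric(m$grid) >= cutoff_nm
  if (!any(keep)) stop("empty-spectrum error: cutoff removes every band")
  spectrum_matrix(m$values[, keep, drop = FALSE],
                  wavelength_grid(as.numeric(m$grid)[keep]), m$labels)
}

# ---- Step 2: percentile baseline subtraction --------------------------------

#' Subtract a per-spectrum percentile baseline
#'
#' For each pixel spectrum the scalar `percentile`-th percentile of its band
#' intensities (linear-interpolation definition, position `q * (p - 1)`) is
#' subtracted from every band. This removes slowly varying additive offsets
#' from dark-current drift and broadband autofluorescence while leaving
#' spectral shape intact.
#'
#' @param m A [spectrum_matrix()] with at least 2 bands.
#' @param percentile Percentile in \[0, 100\] (default 10).
#' @return A baseline-corrected [spectrum_matrix()].
#' @export
subtract_baseline <- function(m, percentile = 10) {
  if (ncol(m$values) < 2L) stop("need at least 2 bands for baseline estimation")
  q <- percentile / 100
  base <- apply(m$values, 1L, stats::quantile, probs = q, type = 7, names = FALSE)
  spectrum_matrix(m$values - base, m$grid, m$labels)
}

# ---- Step 3: negative clipping ----------------------------------------------

#' Clip negative intensities to zero
#'
#' Fluorescence intensity is physically non-negative; negatives introduced by
#' noise or baseline overcorrection are set to zero.
#'
#' @param m A [spectrum_matrix()].
#' @return A [spectrum_matrix()] with `pmax(values, 0)`.
#' @export
clip_negatives <- function(m) {
  spectrum_matrix(pmax(m$values, 0), m$grid, m$labels)
}

# ---- Step 4: area normalization ---------------------------------------------

.trapezoid_weights <- function(x) {
  p <- length(x)
  if (p < 2L) stop("need at least 2 bands for a trapezoid integral")
  w <- numeric(p)
  w[1] <- (x[2] - x[1]) / 2
  w[p] <- (x[p] - x[p - 1]) / 2
  if (p > 2L) w[2:(p - 1)] <- (x[3:p] - x[1:(p - 2)]) / 2
  w
}

#' Normalize each spectrum by its integrated area
#'
#' Each row is divided by its trapezoid-rule integral over the wavelength
#' grid, so that every normalized spectrum integrates to exactly 1. This
#' removes absolute-intensity variation (concentration, surface roughness,
#' illumination) while preserving spectral shape. A constant spectrum on the
#' 480--1000 nm range normalizes to 1/520 per nm.
#'
#' @param m A [spectrum_matrix()] with non-negative values.
#' @return An area-normalized [spectrum_matrix()].
#' @export
area_normalize <- function(m) {
  w <- .trapezoid_weights(as.numeric(m$grid))
  integrals <- as.vector(m$values %*% w)
  zero <- which(integrals <= 0)
  if (length(zero)) {
    stop(sprintf("degenerate-spectrum error: zero integral in row(s) %s",
                 paste(utils::head(zero, 5), collapse = ", ")))
  }
  spectrum_matrix(m$values / integrals, m$grid, m$labels)
}

# ---- Step 5: Savitzky-Golay smoothing ---------------------------------------

.sgolay_operator <- function(p, order, window) {
  # dense p x p smoothing operator replicating signal::sgolayfilt semantics:
  # interior points use the center filter row, terminal half-windows use the
  # polynomial fit over the first/last full window (no mirror padding)
  FF <- signal::sgolay(p = order, n = window)
  k <- floor(window / 2)
  L <- matrix(0, p, p)
  L[1:k, 1:window] <- FF[1:k, ]
  for (i in (k + 1):(p - k)) L[i, (i - k):(i + k)] <- FF[k + 1, ]
  L[(p - k + 1):p, (p - window + 1):p] <- FF[(k + 2):window, ]
  L
}

#' Savitzky-Golay smoothing of each spectrum
#'
#' Least-squares polynomial smoothing (default order 3, window 11 points)
#' applied per row. Attenuates high-frequency noise while preserving peak
#' position, height and width; polynomials up to the filter order are
#' reproduced exactly. Terminal half-windows are smoothed with the
#' polynomial fit over the first/last full window rather than mirror
#' padding, which preserves peaks near the spectral cut.
#'
#' @param m A [spectrum_matrix()] with at least `window` bands.
#' @param order Polynomial order (default 3), must be less than `window`.
#' @param window Odd window length in points (default 11).
#' @return A smoothed [spectrum_matrix()].
#' @export
savgol_smooth <- function(m, order = 3, window = 11) {
  p <- ncol(m$values)
  if (window %% 2 != 1L) stop("window must be odd")
  if (order >= window) stop("order must be less than window")
  if (p < window) {
    stop(sprintf("window-too-large error: %d bands < window %d", p, window))
  }
  L <- .sgolay_operator(p, order, window)
  spectrum_matrix(m$values %*% t(L), m$grid, m$labels)
}

# ---- dB transform (display/export) ------------------------------------------

#' Amplitude decibel transform
#'
#' `20 * log10(x)`, the amplitude-based convention for optical intensity
#' data. Values at or below `1e-6` are mapped to a floor of -120 dB so
#' outputs remain finite. 4100 counts maps to about 72 dB. The transform is
#' for display and export; it does not feed the classification path.
#'
#' @param values Numeric vector, matrix or array of non-negative intensities.
#' @return dB values of the same shape.
#' @examples
#' to_decibel(c(1, 10, 4100))  # 0, 20, ~72.3
#' @export
to_decibel <- function(values) {
  out <- values
  low <- values <= 1e-6
  out[!low] <- 20 * log10(values[!low])
  out[low] <- -120
  out
}

# ---- full pipeline ----------------------------------------------------------

#' Five-step spectral preprocessing pipeline
#'
#' Applies, in this fixed order: (1) laser-band removal below `cutoff_nm`,
#' (2) per-spectrum percentile baseline subtraction, (3) negative clipping,
#' (4) trapezoid area normalization, (5) Savitzky-Golay smoothing. The order
#' matters: e.g. normalization must follow clipping so that row integrals
#' are taken over non-negative spectra.
#'
#' @param m A [spectrum_matrix()] of calibrated spectra on the full grid.
#' @param cutoff_nm Laser-band cutoff in nm (default 480).
#' @param baseline_percentile Baseline percentile (default 10).
#' @param savgol_order Smoothing polynomial order (default 3).
#' @param savgol_window Smoothing window length (default 11).
#' @return A preprocessed [spectrum_matrix()]; the steps applied are
#'   recorded in `attr(, "steps")`.
#' @export
preprocess_pipeline <- function(m, cutoff_nm = 480, baseline_percentile = 10,
                                savgol_order = 3, savgol_window = 11) {
  out <- remove_laser_bands(m, cutoff_nm)
  out <- subtract_baseline(out, baseline_percentile)
  out <- clip_negatives(out)
  out <- area_normalize(out)
  out <- savgol_smooth(out, order = savgol_order, window = savgol_window)
  attr(out, "steps") <- list(
    remove_laser_bands = list(cutoff_nm = cutoff_nm),
    subtract_baseline = list(percentile = baseline_percentile),
    clip_negatives = list(),
    area_normalize = list(rule = "trapezoid"),
    savgol_smooth = list(order = savgol_order, window = savgol_window)
  )
  out
}
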