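# Synthetic LIF-HSI phantom scenes: clean-salt and contaminated pixel
# spectra with the emission structure of sunscreen UV filters, spatially
# clustered contamination, white/dark reference frames and a ground-truth
# mask. Every downstream stage is testable against these scenes without
# instrument data.

.gaussian_peak <- function(x, center, fwhm, amplitude) {
  amplitude * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
}

#' Phantom scene configuration
#'
#' Defaults encode the measurement conditions the generator emulates: a
#' 128-band 400--1000 nm grid; clean salt with a flat 200--400 count
#' background plus a faint reflection of the 450 nm excitation line;
#' contaminated pixels adding a dominant emission peak at ~500 nm
#' (4100 counts, FWHM 40 nm, maximum inside 480--520 nm) with secondary
#' features near 575, 750 and 990 nm at 5--10% of the main amplitude;
#' spatially clustered contamination covering ~57.8% of pixels; additive
#' Gaussian sensor noise and a dark-current offset.
#'
#' @param rows,cols Spatial dimensions (default 200 x 200).
#' @param grid A [wavelength_grid()] (default 128 bands, 400--1000 nm).
#' @param clean_baseline_range Flat background interval in counts
#'   (default 200--400).
#' @param laser_center_nm,laser_fwhm_nm,laser_amplitude Residual laser
#'   line parameters (default 450 nm, 10 nm, 800 counts).
#' @param main_peak List `(center_nm, fwhm_nm, amplitude)` of the dominant
#'   emission peak (default 500 nm, 40 nm, 4100 counts).
#' @param secondary_peaks List of secondary peak lists in the same form.
#' @param contamination_fraction Target contaminated-pixel fraction
#'   (default 0.578).
#' @param correlation_length_px Spatial smoothness of the contamination
#'   field in pixels (default 10).
#' @param noise_sd Additive Gaussian sensor noise in counts (default 30).
#' @param dark_level Dark-current offset in counts (default 100).
#' @param white_level Mean white-reference counts (default 3000).
#' @param white_nonuniformity Peak relative amplitude of the smooth spatial
#'   nonuniformity of the white frame (default 0.02, i.e. <= 2%).
#' @param seed Master RNG seed; all randomness in the scene derives from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(rows = 200, cols = 200,
                           grid = make_wavelength_grid(400, 1000, 128),
                           clean_baseline_range = c(200, 400),
                           laser_center_nm = 450, laser_fwhm_nm = 10,
                           laser_amplitude = 800,
                           main_peak = list(center_nm = 500, fwhm_nm = 40,
                                            amplitude = 4100),
                           secondary_peaks = list(
                             list(center_nm = 575, fwhm_nm = 50, amplitude = 400),
                             list(center_nm = 750, fwhm_nm = 60, amplitude = 250),
                             list(center_nm = 990, fwhm_nm = 20, amplitude = 220)),
                           contamination_fraction = 0.578,
                           correlation_length_px = 10,
                           noise_sd = 30, dark_level = 100,
                           white_level = 3000, white_nonuniformity = 0.02,
                           seed = 1) {
  amps <- c(laser_amplitude, main_peak$amplitude,
            vapply(secondary_peaks, function(p) p$amplitude, numeric(1)))
  if (any(amps < 0)) stop("peak amplitudes must be non-negative")
  if (contamination_fraction < 0 || contamination_fraction > 1) {
    stop("contamination_fraction must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(rows = rows, cols = cols, grid = grid,
                 clean_baseline_range = clean_baseline_range,
                 laser_center_nm = laser_center_nm,
                 laser_fwhm_nm = laser_fwhm_nm,
                 laser_amplitude = laser_amplitude,
                 main_peak = main_peak, secondary_peaks = secondary_peaks,
                 contamination_fraction = contamination_fraction,
                 correlation_length_px = correlation_length_px,
                 noise_sd = noise_sd, dark_level = dark_level,
                 white_level = white_level,
                 white_nonuniformity = white_nonuniformity,
                 seed = seed), class = "phantom_config")
}

# deterministic emission profile (counts) added by contamination at scale 1
.contamination_profile <- function(grid, config) {
  x <- as.numeric(grid)
  prof <- .gaussian_peak(x, config$main_peak$center_nm,
                         config$main_peak$fwhm_nm, config$main_peak$amplitude)
  for (p in config$secondary_peaks) {
    prof <- prof + .gaussian_peak(x, p$center_nm, p$fwhm_nm, p$amplitude)
  }
  prof
}

.laser_profile <- function(grid, config) {
  .gaussian_peak(as.numeric(grid), config$laser_center_nm,
                 config$laser_fwhm_nm, config$laser_amplitude)
}

#' Bands carrying planted contamination signal
#'
#' Indices of grid bands where the deterministic contaminated-minus-clean
#' emission profile reaches at least `threshold` of its maximum. Used to
#' check that sparse loadings recover the planted spectral support.
#'
#' @param config A [phantom_config()].
#' @param threshold Relative amplitude cutoff (default 0.01).
#' @return Integer vector of band indices into `config$grid`.
#' @export
planted_band_support <- function(config, threshold = 0.01) {
  prof <- .contamination_profile(config$grid, config)
  which(prof >= threshold * max(prof))
}

#' Simulate one clean-salt pixel spectrum
#'
#' A flat background level drawn uniformly from the clean baseline range,
#' a Gaussian residual of the excitation laser line, and additive Gaussian
#' sensor noise. No emission features above 480 nm beyond baseline.
#'
#' @param grid A [wavelength_grid()] covering the laser line.
#' @param config A [phantom_config()].
#' @param seed RNG seed for this draw.
#' @return Numeric spectrum in counts, one value per band.
#' @export
clean_salt_spectrum <- function(grid, config = phantom_config(), seed = 1) {
  .with_seed(seed, {
    base <- stats::runif(1, config$clean_baseline_range[1],
                         config$clean_baseline_range[2])
    noise <- stats::rnorm(length(grid), 0, config$noise_sd)
    base + .laser_profile(grid, config) + noise
  })
}

#' Simulate one contaminated (sunscreen residue) pixel spectrum
#'
#' The clean-salt spectrum (identical RNG draws, so `concentration_scale =
#' 0` reproduces [clean_salt_spectrum()] under the same seed) plus the
#' deterministic emission profile scaled linearly by `concentration_scale`:
#' the dominant ~500 nm peak and the secondary 575/750/990 nm features.
#' At default settings and scale 1 the spectral maximum lies inside
#' 480--520 nm at about baseline + 4100 counts.
#'
#' @param grid A [wavelength_grid()] covering 480--1000 nm.
#' @param concentration_scale Non-negative linear amplitude scale
#'   (1 = the reference contamination level).
#' @param config A [phantom_config()].
#' @param seed RNG seed for this draw.
#' @return Numeric spectrum in counts.
#' @export
sunscreen_spectrum <- function(grid, concentration_scale = 1,
                               config = phantom_config(), seed = 1) {
  if (concentration_scale < 0) {
    stop("invalid-parameter error: concentration_scale must be non-negative")
  }
  clean_salt_spectrum(grid, config, seed) +
    concentration_scale * .contamination_profile(grid, config)
}

# row/col Gaussian smoothing operators for the correlated random field
.smoothing_operator <- function(n, len) {
  idx <- seq_len(n)
  K <- stats::dnorm(outer(idx, idx, "-"), sd = len)
  K / rowSums(K)
}

#' Spatially clustered contamination field
#'
#' Thresholds a smoothed Gaussian random field at the empirical quantile of
#' the target fraction, producing connected contamination clusters whose
#' realized contaminated fraction matches the target to within the
#' quantile granularity (well inside +/- 0.02).
#'
#' @param rows,cols Field dimensions.
#' @param target_fraction Desired contaminated fraction in \[0, 1\].
#' @param correlation_length_px Gaussian smoothing length in pixels;
#'   larger values give larger, smoother clusters.
#' @param seed RNG seed.
#' @return A [label_mask()] of 0/1 codes.
#' @export
contamination_field <- function(rows, cols, target_fraction,
                                correlation_length_px = 10, seed = 1) {
  if (target_fraction < 0 || target_fraction > 1) {
    stop("target_fraction must lie in [0, 1]")
  }
  if (target_fraction == 0) return(label_mask(matrix(0L, rows, cols)))
  if (target_fraction == 1) return(label_mask(matrix(1L, rows, cols)))
  .with_seed(seed, {
    w <- matrix(stats::rnorm(rows * cols), rows, cols)
    field <- .smoothing_operator(rows, correlation_length_px) %*% w %*%
      t(.smoothing_operator(cols, correlation_length_px))
    thr <- stats::quantile(field, 1 - target_fraction, names = FALSE)
    label_mask(matrix(as.integer(field > thr), rows, cols))
  })
}

#' Render a full phantom scene
#'
#' Generates the ground-truth contamination mask, per-pixel raw spectra
#' (clean or contaminated by truth label, each with its own baseline draw
#' and sensor noise), adds the dark-current offset, clamps negative draws
#' at zero, and produces matching white and dark reference frames. The
#' white frame is a flat high-count panel response with a smooth spatial
#' nonuniformity of at most `white_nonuniformity`; the dark frame is the
#' dark level plus sensor noise. All randomness derives from
#' `config$seed`, so the same configuration renders bit-identical scenes.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_scene`: list with `cube` (raw
#'   counts [hs_cube()]), `white`, `dark` (reference frames as 3-D
#'   arrays), `truth` (a [label_mask()]), and `config`.
#' @export
render_scene <- function(config = phantom_config()) {
  rows <- config$rows; cols <- config$cols
  grid <- config$grid; nb <- length(grid)
  npix <- rows * cols
  truth <- contamination_field(rows, cols, config$contamination_fraction,
                               config$correlation_length_px,
                               seed = config$seed)
  # truth is row/col indexed; flatten row-major to match cube_to_spectra
  truth_flat <- as.integer(t(unclass(truth)))
  .with_seed(config$seed + 1L, {
    base <- stats::runif(npix, config$clean_baseline_range[1],
                         config$clean_baseline_range[2])
    noise <- matrix(stats::rnorm(npix * nb, 0, config$noise_sd), npix, nb)
    spectra <- base + noise +
      matrix(.laser_profile(grid, config), npix, nb, byrow = TRUE)
    contaminated <- truth_flat == 1L
    if (any(contaminated)) {
      spectra[contaminated, ] <- spectra[contaminated, , drop = FALSE] +
        matrix(.contamination_profile(grid, config), sum(contaminated), nb,
               byrow = TRUE)
    }
    raw <- pmax(spectra + config$dark_level, 0)
    cube_data <- aperm(array(t(raw), dim = c(nb, cols, rows)), c(3, 2, 1))

    # white frame: flat panel response with smooth <= 2% nonuniformity
    wfield <- .smoothing_operator(rows, max(5, rows / 10)) %*%
      matrix(stats::rnorm(npix), rows, cols) %*%
      t(.smoothing_operator(cols, max(5, cols / 10)))
    wfield <- wfield / max(abs(wfield), 1e-12) * config$white_nonuniformity
    white <- array(config$white_level * (1 + wfield), dim = c(rows, cols, nb)) +
      config$dark_level
    dark <- array(pmax(config$dark_level +
                         stats::rnorm(npix * nb, 0, config$noise_sd), 0),
                  dim = c(rows, cols, nb))
    structure(list(
      cube = hs_cube(cube_data, grid,
                     meta = list(source = "phantom", seed = config$seed)),
      white = white, dark = dark, truth = truth, config = config
    ), class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %d x %d pixels, %d bands, %.1f%% contaminated\n",
              x$config$rows, x$config$cols, length(x$config$grid),
              100 * mean(unclass(x$truth) == 1L)))
  invisible(x)
}

#' Reference pair of a phantom scene
#'
#' @param scene A `phantom_scene`.
#' @return A [reference_pair()] of its white and dark frames.
#' @export
scene_refs <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  reference_pair(scene$white, scene$dark)
}
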