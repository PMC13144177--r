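test_that("laser-band removal keeps 111 of 128 bands on the uniform grid", {
  g <- make_wavelength_grid(400, 1000, 128)
  m <- spectrum_matrix(matrix(1, 2, 128), g)
  out <- remove_laser_bands(m)
  expect_equal(ncol(out$values), 111)
  expect_true(all(as.numeric(out$grid) >= 480))

  # half-open rule by hand: 400, 410, ..., 490 -> keep 480 and 490
  g10 <- wavelength_grid(seq(400, 490, by = 10))
  out10 <- remove_laser_bands(spectrum_matrix(matrix(1, 1, 10), g10))
  expect_equal(as.numeric(out10$grid), c(480, 490))

  # grid entirely above the cutoff is untouched
  ghi <- make_wavelength_grid(480, 1000, 20)
  mhi <- spectrum_matrix(matrix(rnorm(20), 1), ghi)
  expect_equal(remove_laser_bands(mhi)$values, mhi$values)

  expect_error(remove_laser_bands(mhi, cutoff_nm = 2000), "empty-spectrum")
})

test_that("percentile baseline subtraction matches the interpolated definition", {
  g <- wavelength_grid(seq(480, 580, by = 10))
  # row 0..10: 10th percentile by linear interpolation is 1.0
  m <- spectrum_matrix(rbind(0:10), g)
  expect_equal(subtract_baseline(m)$values[1, ], (0:10) - 1)
  # constant row maps to zeros
  expect_equal(subtract_baseline(spectrum_matrix(rbind(rep(4.2, 11)), g))$values[1, ],
               rep(0, 11))
  # additive offsets are removed exactly
  r <- rnorm(11)
  expect_equal(subtract_baseline(spectrum_matrix(matrix(r + 100, 1), g))$values,
               subtract_baseline(spectrum_matrix(matrix(r, 1), g))$values)
})

test_that("negative clipping is element-wise and idempotent", {
  g <- make_wavelength_grid(480, 1000, 3)
  m <- spectrum_matrix(rbind(c(-1, 0, 2)), g)
  expect_equal(clip_negatives(m)$values[1, ], c(0, 0, 2))
  expect_equal(clip_negatives(clip_negatives(m))$values, clip_negatives(m)$values)
})

test_that("area normalization gives unit trapezoid integrals and scale invariance", {
  g <- make_wavelength_grid(480, 1000, 111)
  set.seed(9)
  m <- spectrum_matrix(matrix(runif(5 * 111, 0.1, 3), 5), g)
  out <- area_normalize(m)
  ints <- apply(out$values, 1, function(y) trapz_integral(as.numeric(g), y))
  expect_equal(ints, rep(1, 5), tolerance = 1e-9)
  # constant spectrum -> 1 / span (span = 520 nm here)
  const <- area_normalize(spectrum_matrix(matrix(7, 1, 111), g))
  expect_equal(const$values[1, 1], 1 / 520, tolerance = 1e-12)
  # scaling a row by 7 changes nothing; normalization is idempotent
  expect_equal(area_normalize(spectrum_matrix(7 * m$values, g))$values, out$values)
  expect_equal(area_normalize(out)$values, out$values, tolerance = 1e-12)
  expect_error(area_normalize(spectrum_matrix(matrix(0, 1, 111), g)),
               "degenerate-spectrum")
})

test_that("Savitzky-Golay smoothing reproduces cubics and matches the window-fit oracle", {
  g <- make_wavelength_grid(480, 1000, 40)
  x <- seq_along(as.numeric(g))
  cubic <- 2 - 0.5 * x + 0.03 * x^2 - 4e-4 * x^3
  sm <- savgol_smooth(spectrum_matrix(rbind(cubic), g))
  expect_lt(max(abs(sm$values[1, ] - cubic)), 1e-9)
  # constant row unchanged
  expect_equal(savgol_smooth(spectrum_matrix(rbind(rep(3, 40)), g))$values[1, ],
               rep(3, 40), tolerance = 1e-12)
  # unit impulse and a noisy row agree with the brute-force per-window fit
  impulse <- c(rep(0, 19), 1, rep(0, 20))
  expect_equal(savgol_smooth(spectrum_matrix(rbind(impulse), g))$values[1, ],
               savgol_oracle(impulse), tolerance = 1e-9)
  set.seed(4)
  noisy <- rnorm(40)
  expect_equal(savgol_smooth(spectrum_matrix(rbind(noisy), g))$values[1, ],
               savgol_oracle(noisy), tolerance = 1e-9)
  expect_error(savgol_smooth(spectrum_matrix(matrix(1, 1, 8),
                                             make_wavelength_grid(480, 1000, 8))),
               "window-too-large")
})

test_that("decibel transform follows the amplitude convention with a floor", {
  expect_equal(to_decibel(1), 0)
  expect_equal(to_decibel(10), 20)
  expect_equal(to_decibel(4100), 20 * log10(4100))
  expect_equal(round(to_decibel(4100)), 72)
  expect_equal(to_decibel(c(0, 1e-7, 1e-6)), rep(-120, 3))
  m <- matrix(c(100, 0.01), 1)
  expect_equal(to_decibel(m), matrix(c(40, -40), 1))
})

test_that("the pipeline runs steps in a fixed order and is row-independent", {
  cfgp <- phantom_config(seed = 21)
  g <- cfgp$grid
  spectra <- rbind(
    sunscreen_spectrum(g, 1, cfgp, seed = 1),
    sunscreen_spectrum(g, 1, cfgp, seed = 2),
    clean_salt_spectrum(g, cfgp, seed = 3),
    clean_salt_spectrum(g, cfgp, seed = 4))
  m <- spectrum_matrix(spectra, g)
  out <- preprocess_pipeline(m)
  # contaminated argmax survives preprocessing inside the emission window
  peak_nm <- as.numeric(out$grid)[apply(out$values[1:2, ], 1, which.max)]
  expect_true(all(peak_nm >= 480 & peak_nm <= 520))
  # scrambled order (baseline subtraction after normalization) differs
  scrambled <- savgol_smooth(subtract_baseline(area_normalize(clip_negatives(
    remove_laser_bands(m)))))
  expect_false(isTRUE(all.equal(scrambled$values, out$values)))
  # permuting rows commutes with the pipeline
  perm <- c(3, 1, 4, 2)
  out_perm <- preprocess_pipeline(spectrum_matrix(spectra[perm, ], g))
  expect_equal(out_perm$values, out$values[perm, ])
  # all-zero rows trip the area-normalization guard
  expect_error(preprocess_pipeline(spectrum_matrix(matrix(0, 2, length(g)), g)),
               "degenerate-spectrum")
})
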