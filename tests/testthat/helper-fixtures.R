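# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# the reference phantom study scene and its full pipeline run
default_phantom <- function() phantom_config(seed = 7)

default_run <- function() {
  cached_fixture("default_run", function() {
    run_pipeline(run_config(phantom = default_phantom(), seed = 7, folds = 10))
  })
}

# small labeled preprocessed spectra for quick model-level tests
small_labeled_spectra <- function() {
  cached_fixture("small_spectra", function() {
    scene <- render_scene(phantom_config(rows = 60, cols = 60, seed = 3))
    cal <- calibrate(scene$cube, scene_refs(scene))
    draw <- balanced_sample(scene$truth, 120, seed = 3)
    sp <- cube_to_spectra(cal)
    idx <- (draw$row - 1L) * 60L + draw$col
    preprocess_pipeline(spectrum_matrix(sp$values[idx, ], cal$grid, draw$label))
  })
}

# brute-force Savitzky-Golay oracle: per-output-point least-squares
# polynomial fit over the window signal::sgolayfilt semantics prescribe
savgol_oracle <- function(y, order = 3, window = 11) {
  len <- length(y)
  k <- floor(window / 2)
  out <- numeric(len)
  for (i in seq_len(len)) {
    win <- if (i <= k) 1:window
           else if (i > len - k) (len - window + 1):len
           else (i - k):(i + k)
    fit <- stats::lm(y[win] ~ stats::poly(win, order, raw = TRUE))
    out[i] <- unname(stats::predict(fit, data.frame(win = i)))
  }
  out
}

# sparse_pca_model with a prescribed non-zero pattern, for bookkeeping tests
model_with_nnz <- function(nnz, p) {
  V <- matrix(0, p, length(nnz))
  for (j in seq_along(nnz)) V[seq_len(nnz[j]), j] <- 1 / sqrt(nnz[j])
  structure(list(loadings = V, n_components = length(nnz),
                 nonzero_counts = colSums(V != 0), lambda = 0.5),
            class = "sparse_pca_model")
}

trapz_integral <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
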