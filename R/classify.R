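# Soft-margin RBF SVM on sparse-PCA scores. The quadratic-program solver is
# e1071/libsvm; this layer pins the configuration the pipeline depends on:
# C = 1, kernel scale resolved by the median-distance heuristic, predictor
# standardization, class coding 0 = clean / 1 = contaminated.

#' Train the RBF support vector machine
#'
#' Standardizes the score features to zero mean and unit variance, resolves
#' the kernel scale, and trains a soft-margin RBF SVM. With
#' `kernel_scale = "auto"` the scale \eqn{\sigma} is the median pairwise
#' Euclidean distance among the standardized training points (a
#' deterministic heuristic); the RBF kernel is
#' \eqn{K(x, y) = \exp(-\|x-y\|^2 / (2\sigma^2))}.
#'
#' @param scores n x k feature matrix (e.g. from [spca_transform()]).
#' @param labels Per-row class codes: 0 = clean, 1 = contaminated; both
#'   classes must be present.
#' @param C Box constraint (soft-margin cost), default 1.
#' @param kernel_scale `"auto"` or a positive number.
#' @param seed Recorded in the model metadata (training itself is
#'   deterministic).
#' @return An object of class `lif_svm` wrapping the fitted machine with
#'   the standardization parameters and resolved kernel scale.
#' @export
train_svm <- function(scores, labels, C = 1, kernel_scale = "auto", seed = NULL) {
  scores <- as.matrix(unclass(scores))
  labels <- as.integer(labels)
  if (!all(is.finite(scores))) stop("data error: non-finite feature values")
  if (length(unique(labels)) < 2L) {
    stop("class-coverage error: both classes (0 and 1) must be present")
  }
  if (any(table(labels) < 2L)) stop("need at least 2 samples per class")
  if (C <= 0) stop("C must be positive")
  mu <- colMeans(scores)
  sds <- apply(scores, 2L, stats::sd)
  sds[sds == 0] <- 1
  std <- sweep(sweep(scores, 2L, mu, "-"), 2L, sds, "/")
  if (identical(kernel_scale, "auto")) {
    sigma <- stats::median(stats::dist(std))
    if (!is.finite(sigma) || sigma <= 0) {
      stop("degenerate-features error: median pairwise distance is zero")
    }
    policy <- "auto"
  } else {
    sigma <- as.numeric(kernel_scale)
    if (!is.finite(sigma) || sigma <= 0) stop("kernel_scale must be positive")
    policy <- "numeric"
  }
  fit <- e1071::svm(x = std, y = factor(labels, levels = c(0L, 1L)),
                    type = "C-classification", kernel = "radial",
                    cost = C, gamma = 1 / (2 * sigma^2), scale = FALSE)
  structure(list(
    fit = fit,
    feature_means = mu,
    feature_sds = sds,
    C = C,
    kernel_scale = sigma,
    kernel_scale_policy = policy,
    n_per_class = as.vector(table(factor(labels, levels = c(0L, 1L)))),
    seed = seed
  ), class = "lif_svm")
}

#' @export
print.lif_svm <- function(x, ...) {
  cat(sprintf("<lif_svm> RBF, C = %g, sigma = %.4g (%s), trained on %d + %d\n",
              x$C, x$kernel_scale, x$kernel_scale_policy,
              x$n_per_class[1], x$n_per_class[2]))
  invisible(x)
}

#' Predict class codes for score rows
#'
#' @param object A fitted `lif_svm`.
#' @param newdata n x k feature matrix on the training feature space.
#' @param ... Unused.
#' @return Integer vector of class codes (0 = clean, 1 = contaminated).
#' @export
predict.lif_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(unclass(newdata))
  if (ncol(newdata) != length(object$feature_means)) {
    stop(sprintf("dimension error: %d features but model was trained on %d",
                 ncol(newdata), length(object$feature_means)))
  }
  std <- sweep(sweep(newdata, 2L, object$feature_means, "-"),
               2L, object$feature_sds, "/")
  as.integer(as.character(predict(object$fit, std)))
}

#' Stratified cross-validation of the sparse-PCA + SVM pipeline
#'
#' Partitions labeled preprocessed spectra into stratified folds (per-class
#' counts differ by at most one across folds) and, inside each training
#' fold, refits sparse PCA and the SVM from scratch before scoring the held
#' fold. Refitting the feature extractor per fold avoids information
#' leakage from held-out spectra into the loadings.
#'
#' @param X A [spectrum_matrix()] or matrix of preprocessed spectra.
#' @param labels Class codes \{0, 1\} (taken from `X$labels` if omitted).
#' @param folds Number of folds (default 10); must be at least 2.
#' @param k,lambda Sparse PCA configuration (defaults 4 and 0.5).
#' @param C SVM box constraint (default 1).
#' @param seed RNG seed for the fold assignment.
#' @return A list with `per_fold` (data frame of fold-wise accuracy,
#'   precision, recall, f1), `mean`, `sd`.
#' @export
crossval <- function(X, labels = NULL, folds = 10, k = 4, lambda = 0.5,
                     C = 1, seed = 1) {
  Xm <- .as_matrix(X)
  if (is.null(labels) && inherits(X, "spectrum_matrix")) labels <- X$labels
  if (is.null(labels)) stop("labeled spectra required")
  labels <- as.integer(labels)
  if (folds < 2L) stop("validation error: need at least 2 folds")
  fold_id <- .stratified_folds(labels, folds, seed)
  per <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    model <- suppressWarnings(fit_sparse_pca(Xm[tr, , drop = FALSE],
                                             k = k, lambda = lambda))
    svm <- train_svm(spca_transform(model, Xm[tr, , drop = FALSE]),
                     labels[tr], C = C)
    pred <- predict(svm, spca_transform(model, Xm[!tr, , drop = FALSE]))
    truth <- labels[!tr]
    cc <- confusion_counts(tp = sum(pred == 1 & truth == 1),
                           tn = sum(pred == 0 & truth == 0),
                           fp = sum(pred == 1 & truth == 0),
                           fn = sum(pred == 0 & truth == 1))
    mt <- metrics(cc)
    data.frame(fold = f, n = sum(!tr), accuracy = mt$accuracy,
               precision = mt$precision, recall = mt$recall, f1 = mt$f1)
  })
  per <- do.call(rbind, per)
  list(per_fold = per,
       mean = colMeans(per[, c("accuracy", "precision", "recall", "f1")],
                       na.rm = TRUE),
       sd = apply(per[, c("accuracy", "precision", "recall", "f1")], 2L,
                  stats::sd, na.rm = TRUE))
}

#' Pixel-wise classification of a whole cube
#'
#' Runs the full inference chain on every pixel: radiometric calibration,
#' the five-step preprocessing pipeline, projection onto the fitted sparse
#' components, and SVM prediction. Spatial order is pure bookkeeping: the
#' result equals row-wise prediction on the flattened cube.
#'
#' @param cube Raw [hs_cube()].
#' @param refs A [reference_pair()] for calibration, or `NULL` if `cube` is
#'   already calibrated.
#' @param spca A fitted `sparse_pca_model`.
#' @param svm A fitted `lif_svm`.
#' @param cutoff_nm,baseline_percentile,savgol_order,savgol_window
#'   Preprocessing parameters (must match those used in training).
#' @return A [label_mask()] classification map (0 = clean,
#'   1 = contaminated) with the cube's spatial shape.
#' @export
classify_cube <- function(cube, refs, spca, svm, cutoff_nm = 480,
                          baseline_percentile = 10, savgol_order = 3,
                          savgol_window = 11) {
  if (!is.null(refs)) cube <- calibrate(cube, refs)
  d <- dim(cube$data)
  m <- preprocess_pipeline(cube_to_spectra(cube), cutoff_nm = cutoff_nm,
                           baseline_percentile = baseline_percentile,
                           savgol_order = savgol_order,
                           savgol_window = savgol_window)
  pred <- predict(svm, spca_transform(spca, m))
  label_mask(matrix(pred, nrow = d[1], ncol = d[2], byrow = TRUE))
}
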