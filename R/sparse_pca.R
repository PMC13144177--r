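# Sparse PCA by power iteration with an adaptive relative soft-threshold
# and Hotelling deflation. This is the package's core feature extractor.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Soft-thresholding (shrinkage) operator
#'
#' Element-wise `sign(z) * max(|z| - tau, 0)`: coefficients with magnitude
#' below `tau` are set exactly to zero, the rest are shrunk toward zero.
#' This is the proximal operator of the L1 penalty and the mechanism that
#' produces sparse loadings.
#'
#' @param z Numeric coefficient vector.
#' @param tau Threshold, `tau >= 0`.
#' @return Thresholded vector of the same length.
#' @examples
#' soft_threshold(c(3, -1, 0.5), 1)  # 2, 0, 0
#' @export
soft_threshold <- function(z, tau) {
  if (tau < 0) stop("tau must be non-negative")
  sign(z) * pmax(abs(z) - tau, 0)
}

.as_matrix <- function(X) {
  if (inherits(X, "spectrum_matrix")) X$values else as.matrix(X)
}

.standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  if (is.null(scale)) {
    scale <- apply(Xc, 2L, stats::sd)
    scale[scale == 0] <- 1  # zero-variance columns stay at zero
  }
  list(values = sweep(Xc, 2L, scale, "/"), center = center, scale = scale)
}

.sign_fix <- function(v) {
  j <- which.max(abs(v))
  if (v[j] < 0) -v else v
}

#' Fit sparse PCA with adaptive relative soft-thresholding
#'
#' Extracts `k` sparse loading vectors from an n x p spectrum matrix by a
#' power-iteration scheme. Columns are centered and scaled to unit variance
#' first. For each component the update is
#' \deqn{z = X^T (X v), \quad \tau = \lambda \max_j |z_j|, \quad
#'       v \leftarrow S(z, \tau) / \|S(z, \tau)\|_2}
#' where \eqn{S} is [soft_threshold()]. Rescaling the threshold to each
#' component's own signal magnitude keeps the sparsity level comparable
#' across components of very different variance, so low-intensity secondary
#' emission bands are not suppressed by a threshold calibrated on the
#' dominant peak. After convergence the matrix is deflated by Hotelling's
#' rule \eqn{X \leftarrow X - (X v) v^T} before the next component.
#'
#' At `lambda = 0` the threshold vanishes and the procedure reduces to plain
#' power iteration, recovering ordinary principal components. For
#' `lambda >= 1` the threshold reaches `max|z|` and would zero every
#' coefficient; the fallback then retains the single largest-magnitude
#' coefficient (with a warning), keeping grid scans over lambda total.
#'
#' @param X A [spectrum_matrix()] or numeric matrix (n >= 2 rows).
#' @param k Number of components to extract.
#' @param lambda Sparsity parameter in \[0, 1); values >= 1 trigger the
#'   single-coefficient fallback.
#' @param tol Convergence tolerance on `min(||v - v_old||, ||v + v_old||)`
#'   (default 1e-6).
#' @param max_iter Iteration cap per component (default 500).
#' @return An object of class `sparse_pca_model` with fields `loadings`
#'   (p x k, unit-norm columns, sign-fixed so the largest-magnitude entry is
#'   positive), `column_means`, `column_scales`, `lambda`, `n_components`,
#'   `iterations`, `converged`, `explained_variance` (variance of each score
#'   column; non-additive for sparse, non-orthogonal loadings),
#'   `total_variance`, `nonzero_counts`, and the training `grid` if the
#'   input carried one.
#' @seealso [spca_transform()], [sparsity_stats()], [fit_standard_pca()]
#' @export
fit_sparse_pca <- function(X, k = 4, lambda = 0.5, tol = 1e-6, max_iter = 500) {
  grid <- if (inherits(X, "spectrum_matrix")) X$grid else NULL
  X <- .as_matrix(X)
  if (!all(is.finite(X))) stop("data error: non-finite values in input")
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 spectra")
  if (k < 1L || k > p) stop("k must be between 1 and the number of bands")
  if (lambda < 0) stop("lambda must be non-negative")

  std <- .standardize(X)
  Xs <- std$values
  Xd <- Xs
  V <- matrix(0, p, k)
  iters <- integer(k); conv <- logical(k)
  expl <- numeric(k); nnz <- integer(k)
  fallback_used <- FALSE

  for (j in seq_len(k)) {
    v <- svd(Xd, nu = 0L, nv = 1L)$v[, 1]  # deterministic initialization
    it <- 0L; converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      z <- drop(crossprod(Xd, Xd %*% v))
      tau <- lambda * max(abs(z))
      s <- soft_threshold(z, tau)
      if (all(s == 0)) {
        # threshold at or above max|z|: keep the dominant coefficient
        fallback_used <- TRUE
        s[which.max(abs(z))] <- z[which.max(abs(z))]
      }
      v_new <- s / sqrt(sum(s^2))
      delta <- min(sqrt(sum((v_new - v)^2)), sqrt(sum((v_new + v)^2)))
      v <- v_new
      if (delta < tol) { converged <- TRUE; break }
    }
    v <- .sign_fix(v)
    V[, j] <- v
    iters[j] <- it; conv[j] <- converged
    nnz[j] <- sum(v != 0)
    expl[j] <- stats::var(drop(Xs %*% v))
    Xd <- Xd - (Xd %*% v) %*% t(v)
  }
  if (fallback_used) {
    warning("lambda >= 1 regime: soft threshold zeroed all coefficients; ",
            "kept the single largest-magnitude coefficient")
  }
  structure(list(
    loadings = V,
    column_means = std$center,
    column_scales = std$scale,
    lambda = lambda,
    n_components = k,
    iterations = iters,
    converged = conv,
    explained_variance = expl,
    total_variance = sum(apply(Xs, 2L, stats::var)),
    nonzero_counts = nnz,
    grid = grid,
    dense = FALSE
  ), class = "sparse_pca_model")
}

#' @export
print.sparse_pca_model <- function(x, ...) {
  cat(sprintf("<sparse_pca_model> k = %d, lambda = %g%s\n", x$n_components,
              x$lambda, if (isTRUE(x$dense)) " (dense baseline)" else ""))
  cat(sprintf("  nonzero loadings per component: %s\n",
              paste(x$nonzero_counts, collapse = ", ")))
  cat(sprintf("  overall sparsity: %.1f%%\n", sparsity_stats(x)$overall_pct))
  invisible(x)
}

#' Dense PCA baseline
#'
#' Exact eigendecomposition (via SVD of the standardized matrix) returning
#' the same model structure as [fit_sparse_pca()] with `lambda` recorded as
#' 0. Loadings are orthonormal and dense; used as the comparison baseline
#' for the sparse extractor.
#'
#' @inheritParams fit_sparse_pca
#' @return A `sparse_pca_model` with dense loadings.
#' @export
fit_standard_pca <- function(X, k = 4) {
  grid <- if (inherits(X, "spectrum_matrix")) X$grid else NULL
  X <- .as_matrix(X)
  if (!all(is.finite(X))) stop("data error: non-finite values in input")
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 spectra")
  if (k < 1L || k > min(n, p)) stop("k out of range")
  std <- .standardize(X)
  sv <- svd(std$values, nu = 0L, nv = k)
  V <- apply(sv$v[, seq_len(k), drop = FALSE], 2L, .sign_fix)
  structure(list(
    loadings = V,
    column_means = std$center,
    column_scales = std$scale,
    lambda = 0,
    n_components = k,
    iterations = rep(1L, k),
    converged = rep(TRUE, k),
    explained_variance = sv$d[seq_len(k)]^2 / (n - 1),
    total_variance = sum(apply(std$values, 2L, stats::var)),
    nonzero_counts = colSums(V != 0),
    grid = grid,
    dense = TRUE
  ), class = "sparse_pca_model")
}

#' Project spectra onto fitted sparse components
#'
#' Standardizes `X` with the training column means/scales and multiplies by
#' the loading matrix.
#'
#' @param model A `sparse_pca_model`.
#' @param X A [spectrum_matrix()] or matrix on the training band grid.
#' @return An n x k score matrix (class `score_matrix`, with the model
#'   attached as attribute `model`).
#' @export
spca_transform <- function(model, X) {
  stopifnot(inherits(model, "sparse_pca_model"))
  X <- .as_matrix(X)
  if (ncol(X) != nrow(model$loadings)) {
    stop(sprintf("dimension error: %d bands but model was fit on %d",
                 ncol(X), nrow(model$loadings)))
  }
  Xs <- .standardize(X, center = model$column_means, scale = model$column_scales)$values
  scores <- Xs %*% model$loadings
  colnames(scores) <- paste0("SPC", seq_len(ncol(scores)))
  structure(scores, class = c("score_matrix", "matrix"), model = model)
}

#' Sparsity report for a fitted model
#'
#' Counts exact zeros in the loading matrix. Per-component sparsity is
#' `(p - nnz) / p * 100`; overall sparsity pools all `k * p` coefficients.
#' Percentages are rounded to one decimal in the report (e.g. 118 non-zero
#' of 444 total gives 73.4% overall).
#'
#' @param model A `sparse_pca_model`.
#' @return A list with `per_component` (data frame: component, nonzero,
#'   sparsity_pct), `overall_nonzero`, `overall_total`, `overall_pct`.
#' @export
sparsity_stats <- function(model) {
  stopifnot(inherits(model, "sparse_pca_model"))
  p <- nrow(model$loadings); k <- model$n_components
  nnz <- model$nonzero_counts
  per <- data.frame(
    component = seq_len(k),
    nonzero = nnz,
    sparsity_pct = round((p - nnz) / p * 100, 1)
  )
  list(per_component = per,
       overall_nonzero = sum(nnz),
       overall_total = k * p,
       overall_pct = round((k * p - sum(nnz)) / (k * p) * 100, 1))
}

# ---- hyperparameter scans ---------------------------------------------------

.stratified_folds <- function(labels, folds, seed) {
  .with_seed(seed, {
    assignment <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < folds) {
        stop(sprintf("validation error: class %s has %d samples, fewer than %d folds",
                     cls, length(idx), folds))
      }
      assignment[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
    assignment
  })
}

# CV accuracy of the sparse-PCA + SVM pipeline, refitting the feature
# extractor inside each training fold (no leakage). Components from the
# deflation scheme are nested, so one fit at max(k_values) serves all k.
.cv_pipeline_accuracy <- function(X, labels, k_values, lambda, folds, fold_id, C = 1) {
  k_max <- max(k_values)
  acc <- matrix(NA_real_, nrow = folds, ncol = length(k_values))
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    model <- suppressWarnings(fit_sparse_pca(X[tr, , drop = FALSE], k = k_max,
                                             lambda = lambda))
    sc_tr <- spca_transform(model, X[tr, , drop = FALSE])
    sc_te <- spca_transform(model, X[te, , drop = FALSE])
    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      svm <- train_svm(sc_tr[, seq_len(k), drop = FALSE], labels[tr])
      pred <- predict(svm, sc_te[, seq_len(k), drop = FALSE])
      acc[f, ki] <- mean(pred == labels[te])
    }
  }
  acc
}

#' Select the number of sparse components by cross-validation
#'
#' Scans `k` over `k_range`, refitting sparse PCA and the SVM inside each
#' training fold, and picks the smallest `k` whose mean CV accuracy is
#' within one standard error of the best (the accuracy-plateau rule).
#' Scree eigenvalues and cumulative explained variance from the dense PCA
#' are returned as diagnostics.
#'
#' @param X A [spectrum_matrix()] or matrix of preprocessed spectra.
#' @param labels Per-row class codes \{0, 1\}.
#' @param k_range Candidate component counts (default 1:12).
#' @param lambda Sparsity parameter used during the scan (default 0.5).
#' @param folds Number of stratified CV folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return A list with `k` (selected), `table` (k, mean/sd CV accuracy),
#'   `scree` (eigenvalues), `cumulative_variance` (percent).
#' @export
select_k <- function(X, labels, k_range = 1:12, lambda = 0.5, folds = 5,
                     seed = 1) {
  Xm <- .as_matrix(X)
  if (is.null(labels) && inherits(X, "spectrum_matrix")) labels <- X$labels
  if (is.null(labels)) stop("labeled spectra required")
  fold_id <- .stratified_folds(labels, folds, seed)
  k_range <- sort(unique(as.integer(k_range)))
  acc <- .cv_pipeline_accuracy(Xm, labels, k_range, lambda, folds, fold_id)
  mean_acc <- colMeans(acc)
  sd_acc <- apply(acc, 2L, stats::sd)
  best <- which.max(mean_acc)
  threshold <- mean_acc[best] - sd_acc[best] / sqrt(folds)
  k_sel <- k_range[min(which(mean_acc >= threshold))]
  dense <- fit_standard_pca(Xm, k = min(max(k_range), min(dim(Xm)) - 1L))
  eig <- dense$explained_variance
  list(
    k = k_sel,
    table = data.frame(k = k_range, cv_accuracy = mean_acc, cv_sd = sd_acc),
    scree = eig,
    cumulative_variance = cumsum(eig) / dense$total_variance * 100
  )
}

#' Scan the sparsity parameter lambda
#'
#' Evaluates each candidate lambda by (a) the sparsity of a full-data fit
#' and (b) stratified CV accuracy of the sparse-PCA + SVM pipeline refit per
#' fold. Selects the largest lambda whose mean CV accuracy is within one
#' standard error of the best, i.e. maximal interpretability at no
#' performance cost. Lambda values >= 1 force the single-coefficient
#' fallback and are flagged in the table.
#'
#' @inheritParams select_k
#' @param lambda_grid Candidate lambdas (default the 8-point grid
#'   0.001--2.0).
#' @param k Number of components (default 4).
#' @return A list with `lambda` (selected) and `table` (lambda, overall
#'   sparsity percent, mean non-zero loadings per component, CV accuracy
#'   mean/sd, fallback flag).
#' @export
scan_lambda <- function(X, labels,
                        lambda_grid = c(0.001, 0.005, 0.010, 0.050, 0.100,
                                        0.500, 1.000, 2.000),
                        k = 4, folds = 5, seed = 1) {
  Xm <- .as_matrix(X)
  if (is.null(labels) && inherits(X, "spectrum_matrix")) labels <- X$labels
  if (is.null(labels)) stop("labeled spectra required")
  fold_id <- .stratified_folds(labels, folds, seed)
  rows <- lapply(lambda_grid, function(lam) {
    fit <- suppressWarnings(fit_sparse_pca(Xm, k = k, lambda = lam))
    st <- sparsity_stats(fit)
    acc <- .cv_pipeline_accuracy(Xm, labels, k, lam, folds, fold_id)
    data.frame(lambda = lam,
               sparsity_pct = st$overall_pct,
               mean_nonzero = mean(fit$nonzero_counts),
               cv_accuracy = mean(acc),
               cv_sd = stats::sd(acc),
               fallback = lam >= 1)
  })
  tab <- do.call(rbind, rows)
  best <- which.max(tab$cv_accuracy)
  threshold <- tab$cv_accuracy[best] - tab$cv_sd[best] / sqrt(folds)
  lam_sel <- max(tab$lambda[tab$cv_accuracy >= threshold])
  list(lambda = lam_sel, table = tab)
}
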