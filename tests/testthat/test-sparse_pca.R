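test_that("soft-thresholding matches hand cases and shrinks monotonically", {
  expect_equal(soft_threshold(c(3, -1, 0.5), 1), c(2, 0, 0))
  z <- c(-2.5, 0.3, 4, -0.1)
  expect_equal(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(z, 10), rep(0, 4))
  expect_error(soft_threshold(z, -1), "non-negative")
  # nnz under the adaptive threshold is non-increasing in lambda
  lambdas <- seq(0, 1, by = 0.05)
  nnz <- vapply(lambdas,
                function(l) sum(soft_threshold(z, l * max(abs(z))) != 0),
                numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("lambda = 0 reduces to ordinary PCA (eigendecomposition oracle)", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(5:20, 1); p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    ks <- min(3, p, n - 1)
    sparse <- fit_sparse_pca(X, k = ks, lambda = 0)
    dense <- fit_standard_pca(X, k = ks)
    cosines <- abs(colSums(sparse$loadings * dense$loadings))
    expect_true(all(cosines > 1 - 1e-6))
  }
})

test_that("hand-worked two-band example recovers axis-aligned components", {
  X <- rbind(c(2, 0), c(-2, 0), c(0, 0.1), c(0, -0.1))
  m <- fit_sparse_pca(X, k = 2, lambda = 0.5)
  expect_equal(m$loadings[, 1], c(1, 0))
  expect_equal(m$loadings[, 2], c(0, 1))
})

test_that("loadings are unit norm, sign-fixed, and deflation annihilates them", {
  set.seed(55)
  X <- matrix(rnorm(30 * 8), 30, 8)
  m <- fit_sparse_pca(X, k = 4, lambda = 0.3)
  norms <- sqrt(colSums(m$loadings^2))
  expect_equal(norms, rep(1, 4), tolerance = 1e-9)
  for (j in 1:4) {
    v <- m$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)  # sign convention
  }
  # Hotelling deflation maps each component to zero
  Xs <- scale(X)
  attributes(Xs)[c("scaled:center", "scaled:scale")] <- NULL
  Xd <- Xs
  for (j in 1:4) {
    v <- m$loadings[, j]
    Xd_next <- Xd - (Xd %*% v) %*% t(v)
    expect_lt(sqrt(sum((Xd_next %*% v)^2)), 1e-9 * sqrt(sum(Xs^2)))
    Xd <- Xd_next
  }
  expect_true(all(m$nonzero_counts >= 1))
})

test_that("projection uses stored standardization and reproduces score variance", {
  pp <- small_labeled_spectra()
  m <- fit_sparse_pca(pp, k = 4, lambda = 0.5)
  sc <- spca_transform(m, pp)
  expect_equal(unname(apply(unclass(sc), 2, var)), m$explained_variance)
  # a row equal to the column means projects to the origin
  sc0 <- spca_transform(m, matrix(m$column_means, 1))
  expect_equal(unname(unclass(sc0)[1, ]), rep(0, 4))
  # duplicated rows give duplicated scores
  two <- spca_transform(m, pp$values[c(1, 1), ])
  expect_equal(unclass(two)[1, ], unclass(two)[2, ])
  expect_error(spca_transform(m, matrix(1, 2, 5)), "dimension error")
})

test_that("sparsity bookkeeping reports exact-zero counts with 1-dp rounding", {
  m <- model_with_nnz(c(98L, 7L, 7L, 6L), p = 111)
  st <- sparsity_stats(m)
  expect_equal(st$overall_nonzero, 118)
  expect_equal(st$overall_total, 444)
  expect_equal(st$overall_pct, 73.4)
  expect_equal(st$per_component$sparsity_pct, c(11.7, 93.7, 93.7, 94.6))
  # dense loadings -> 0% sparsity
  dense <- model_with_nnz(c(111L, 111L), p = 111)
  expect_equal(sparsity_stats(dense)$overall_pct, 0)
})

test_that("dense PCA baseline is orthonormal with non-increasing variances", {
  set.seed(77)
  X <- matrix(rnorm(40 * 12), 40, 12)
  m <- fit_standard_pca(X, k = 5)
  expect_equal(crossprod(m$loadings), diag(5), tolerance = 1e-9)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
})

test_that("lambda >= 1 falls back to the single dominant coefficient with a warning", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  expect_warning(m <- fit_sparse_pca(X, k = 2, lambda = 1.5), "fallback|largest")
  expect_true(all(m$nonzero_counts == 1))
})

test_that("component selection and lambda scan are deterministic and sensible", {
  pp <- small_labeled_spectra()
  sk <- select_k(pp, pp$labels, k_range = 1:5, folds = 5, seed = 3)
  sk2 <- select_k(pp, pp$labels, k_range = 1:5, folds = 5, seed = 3)
  expect_identical(sk, sk2)
  # two dominant planted factors: plateau is reached by k <= 3
  expect_lte(sk$k, 3)
  expect_equal(select_k(pp, pp$labels, k_range = 1, folds = 5, seed = 3)$k, 1)
  expect_true(all(diff(sk$cumulative_variance) >= -1e-9))

  sl <- suppressWarnings(
    scan_lambda(pp, pp$labels, k = 4, folds = 5, seed = 3))
  expect_identical(sl,
    suppressWarnings(scan_lambda(pp, pp$labels, k = 4, folds = 5, seed = 3)))
  # sparsity is non-decreasing in lambda (ties allowed)
  expect_true(all(diff(sl$table$sparsity_pct) >= -1e-9))
  expect_lt(sl$table$sparsity_pct[1], 5)  # near-zero shrinkage at lambda = 0.001
  expect_true(all(sl$table$fallback == (sl$table$lambda >= 1)))
})

test_that("non-finite input is rejected", {
  X <- matrix(rnorm(20), 5, 4); X[2, 2] <- NA
  expect_error(fit_sparse_pca(X, k = 1, lambda = 0.1), "data error")
  expect_error(fit_standard_pca(X, k = 1), "data error")
})
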