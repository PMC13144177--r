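test_that("ROI extraction honors the (x, y) convention and bounds", {
  g <- make_wavelength_grid(480, 1000, 3)
  set.seed(6)
  cube <- hs_cube(array(rnorm(400 * 360 * 3), c(360, 400, 3)), g)
  roi <- roi_spec(c(339, 300), width = 30, height = 30, label = 0L)
  m <- extract_roi(cube, roi)
  expect_equal(nrow(m$values), 900)
  expect_true(all(m$labels == 0L))
  # (x = 339 -> col, y = 300 -> row); first row of the block is pixel (300, 339)
  expect_equal(m$values[1, ], cube$data[300, 339, ])
  # 1 x 1 ROI is that pixel's spectrum
  one <- extract_roi(cube, roi_spec(c(10, 20), 1, 1, label = 1L))
  expect_equal(one$values[1, ], cube$data[20, 10, ])
  # out of bounds on a 300-column image
  small <- hs_cube(array(0, c(360, 300, 3)), g)
  expect_error(extract_roi(small, roi), "bounds error")
})

test_that("erosion shrinks class-1 regions into unlabeled borders", {
  m <- matrix(0L, 9, 9)
  m[3:7, 3:6] <- 1L  # solid 5 x 4 rectangle
  er <- erode_mask(label_mask(m), 1)
  core <- unclass(er) == 1L
  expect_equal(sum(core), 6)  # 3 x 2 core
  expect_true(all(core[4:6, 4:5]))
  expect_true(all(unclass(er)[m == 1L & !core] == 255L))
  expect_true(all(unclass(er)[m == 0L] == 0L))
  # radius 0 is the identity; empty class-1 region unchanged
  expect_identical(unclass(erode_mask(label_mask(m), 0)), m)
  zeros <- label_mask(matrix(0L, 4, 4))
  expect_identical(unclass(erode_mask(zeros, 1)), unclass(zeros))
  # border-touching regions lose their border pixels; the center survives
  b <- matrix(1L, 3, 3)
  eb <- unclass(erode_mask(label_mask(b), 1))
  expect_equal(eb[2, 2], 1L)
  expect_true(all(eb[-5] == 255L))
  # eroded class-1 set is a subset of the input set
  set.seed(3)
  r <- label_mask(matrix(sample(c(0L, 1L), 100, TRUE), 10, 10))
  er2 <- erode_mask(r, 1)
  expect_true(all(unclass(r)[unclass(er2) == 1L] == 1L))
})

test_that("balanced sampling draws exact per-class counts reproducibly", {
  set.seed(2)
  m <- label_mask(matrix(sample(c(0L, 1L, 255L), 120 * 120, TRUE,
                                prob = c(0.45, 0.45, 0.1)), 120, 120))
  s <- balanced_sample(m, 2000, seed = 9)
  expect_equal(nrow(s), 4000)
  expect_equal(as.vector(table(s$label)), c(2000, 2000))
  # labels at the drawn coordinates match the mask
  expect_true(all(unclass(m)[cbind(s$row, s$col)] == s$label))
  expect_identical(balanced_sample(m, 2000, seed = 9), s)
  expect_error(balanced_sample(m, 10000, seed = 1), "sampling error")
})

test_that("confusion counting excludes unlabeled truth and matches hand counts", {
  truth <- label_mask(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  pred <- label_mask(matrix(c(1L, 0L, 1L, 0L), 2, 2))
  cc <- confusion(pred, truth)
  expect_equal(unclass(cc), list(tp = 1, tn = 1, fp = 1, fn = 1))
  # identity and complement
  eq <- confusion(truth, truth)
  expect_equal(eq$fp + eq$fn, 0)
  comp <- confusion(label_mask(1L - unclass(truth)), truth)
  expect_equal(comp$tp + comp$tn, 0)
  # unlabeled pixels drop out of the accounting
  t2 <- label_mask(matrix(c(1L, 255L, 0L, 255L), 2, 2))
  cc2 <- confusion(pred, t2)
  expect_equal(cc2$tp + cc2$tn + cc2$fp + cc2$fn, 2)
  expect_error(confusion(pred, label_mask(matrix(0L, 3, 3))), "shape mismatch")
})

test_that("metrics implement the four standard formulas with undefined flags", {
  mt <- metrics(confusion_counts(50, 50, 0, 0))
  expect_equal(c(mt$accuracy, mt$precision, mt$recall, mt$f1), rep(1, 4))
  mt2 <- metrics(confusion_counts(25, 25, 25, 25))
  expect_equal(c(mt2$accuracy, mt2$precision, mt2$recall, mt2$f1), rep(0.5, 4))
  # no predicted positives -> precision undefined, flagged not zeroed
  mt3 <- metrics(confusion_counts(0, 10, 0, 5))
  expect_true(is.na(mt3$precision))
  expect_true("precision" %in% mt3$undefined)
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "empty-comparison")
  # balanced-truth identity: accuracy = (recall + specificity) / 2
  cc <- confusion_counts(1894, 1972, 28, 106)
  m4 <- metrics(cc)
  spec <- cc$tn / (cc$tn + cc$fp)
  expect_equal(m4$accuracy, (m4$recall + spec) / 2, tolerance = 1e-12)
})

test_that("metrics and confusion are invariant under joint spatial permutation", {
  set.seed(14)
  truth <- label_mask(matrix(sample(c(0L, 1L, 255L), 64, TRUE), 8, 8))
  pred <- label_mask(matrix(sample(c(0L, 1L), 64, TRUE), 8, 8))
  perm <- sample(64)
  truth_p <- label_mask(matrix(unclass(truth)[perm], 8, 8))
  pred_p <- label_mask(matrix(unclass(pred)[perm], 8, 8))
  expect_equal(unclass(confusion(pred_p, truth_p)), unclass(confusion(pred, truth)))
})

test_that("class fractions sum to one over labeled pixels", {
  checker <- label_mask(matrix(c(0L, 1L), 10, 10))
  expect_equal(unname(class_fraction(checker)), c(0.5, 0.5))
  all_clean <- label_mask(matrix(0L, 5, 5))
  expect_equal(class_fraction(all_clean)[["contaminated"]], 0)
  with_255 <- label_mask(matrix(c(1L, 255L), 4, 4))
  expect_equal(class_fraction(with_255)[["contaminated"]], 1)
  expect_equal(sum(class_fraction(with_255, include_unlabeled = TRUE)), 1)
  expect_error(class_fraction(label_mask(matrix(255L, 2, 2))), "unlabeled")
})

test_that("error maps categorize every pixel consistently with the confusion", {
  truth <- label_mask(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  pred <- label_mask(matrix(c(1L, 0L, 1L, 0L), 2, 2))
  em <- error_map(pred, truth)
  expect_setequal(as.vector(em$categories), c("TP", "FN", "FP", "TN"))
  counts <- table(em$categories)
  cc <- em$counts
  expect_equal(unname(counts[c("TP", "TN", "FP", "FN")]),
               unname(as.table(c(cc$tp, cc$tn, cc$fp, cc$fn))))
  # perfect prediction -> only TP/TN categories
  em2 <- error_map(truth, truth)
  expect_true(all(em2$categories %in% c("TP", "TN")))
  # unlabeled truth renders black
  t3 <- label_mask(matrix(c(1L, 255L), 1, 2))
  p3 <- label_mask(matrix(c(1L, 0L), 1, 2))
  expect_equal(error_map(p3, t3)$categories[1, 2], "unlabeled")
  # PNG export round-trips the palette
  td <- withr::local_tempdir()
  path <- write_error_map(em, file.path(td, "em.png"))
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(2, 2))
})
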