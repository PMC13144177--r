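# ROI harvesting, ground-truth hygiene and spatial evaluation metrics.

#' Rectangular region-of-interest specification
#'
#' Fixed-size sampling windows used to harvest labeled training spectra
#' (the standard window is 30 x 30 = 900 pixels). By convention imaging
#' software reports ROI origins as (x, y) = (column, row); set
#' `origin_is_xy = FALSE` if the origin is already (row, column). Origins
#' are 1-based and windows are inclusive.
#'
#' @param origin Length-2 integer vector, the ROI's top-left corner.
#' @param width,height Window size in pixels (default 30 x 30).
#' @param label Class code for every pixel in the ROI (0 or 1).
#' @param origin_is_xy Whether `origin` is (col, row) (default) or
#'   (row, col).
#' @return An object of class `roi_spec` with fields `row`, `col`,
#'   `width`, `height`, `label`.
#' @export
roi_spec <- function(origin, width = 30, height = 30, label,
                     origin_is_xy = TRUE) {
  if (width < 1L || height < 1L) stop("ROI must be at least 1 x 1")
  if (!label %in% c(0L, 1L)) stop("ROI label must be 0 or 1")
  origin <- as.integer(origin)
  if (origin_is_xy) {
    col <- origin[1]; row <- origin[2]
  } else {
    row <- origin[1]; col <- origin[2]
  }
  structure(list(row = row, col = col, width = as.integer(width),
                 height = as.integer(height), label = as.integer(label)),
            class = "roi_spec")
}

#' Extract ROI pixel spectra from a cube
#'
#' @param cube An [hs_cube()].
#' @param roi A [roi_spec()]; must lie fully inside the image.
#' @return A [spectrum_matrix()] with `width * height` rows, labeled per
#'   the ROI.
#' @export
extract_roi <- function(cube, roi) {
  stopifnot(inherits(cube, "hs_cube"), inherits(roi, "roi_spec"))
  d <- dim(cube$data)
  r2 <- roi$row + roi$height - 1L
  c2 <- roi$col + roi$width - 1L
  if (roi$row < 1L || roi$col < 1L || r2 > d[1] || c2 > d[2]) {
    stop(sprintf("bounds error: ROI rows %d-%d cols %d-%d outside %d x %d image",
                 roi$row, r2, roi$col, c2, d[1], d[2]))
  }
  block <- cube$data[roi$row:r2, roi$col:c2, , drop = FALSE]
  m <- matrix(aperm(block, c(2, 1, 3)), nrow = roi$width * roi$height,
              ncol = d[3])
  spectrum_matrix(m, cube$grid, labels = rep(roi$label, nrow(m)))
}

#' Erode the contaminated region of a mask
#'
#' Morphological erosion of the class-1 (contaminated) region by a square
#' structuring element of half-width `radius` (3 x 3 for radius 1,
#' 8-connectivity). Class-1 pixels removed by the erosion become unlabeled
#' (255), which discards ambiguous mixed pixels at region boundaries; the
#' image border is treated as background, so class-1 regions touching the
#' border lose their border pixels.
#'
#' @param mask A [label_mask()].
#' @param radius Erosion radius in pixels (default 1); 0 is the identity.
#' @return The eroded [label_mask()].
#' @export
erode_mask <- function(mask, radius = 1) {
  stopifnot(inherits(mask, "label_mask"))
  if (radius < 0) stop("radius must be non-negative")
  if (radius == 0) return(mask)
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L * radius, nc + 2L * radius)
  pad[(radius + 1L):(radius + nr), (radius + 1L):(radius + nc)] <- (m == 1L)
  core <- matrix(TRUE, nr, nc)
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      core <- core & pad[(radius + 1L + dr):(radius + nr + dr),
                         (radius + 1L + dc):(radius + nc + dc)]
    }
  }
  out <- m
  out[m == 1L & !core] <- 255L
  label_mask(out)
}

#' Balanced random sampling of labeled pixels
#'
#' Draws exactly `n_per_class` pixels per class (0 and 1), uniformly
#' without replacement, from the labeled pixels of a ground-truth mask
#' (unlabeled 255 pixels are ignored). The standard validation design is
#' 2000 + 2000.
#'
#' @param mask A [label_mask()].
#' @param n_per_class Number of pixels to draw from each class.
#' @param seed RNG seed; the same seed reproduces the same draw.
#' @return A data frame with columns `row`, `col`, `label`.
#' @export
balanced_sample <- function(mask, n_per_class, seed = 1) {
  stopifnot(inherits(mask, "label_mask"))
  m <- unclass(mask)
  .with_seed(seed, {
    out <- lapply(c(0L, 1L), function(cls) {
      idx <- which(m == cls)
      if (length(idx) < n_per_class) {
        stop(sprintf("sampling error: class %d has only %d labeled pixels, need %d",
                     cls, length(idx), n_per_class))
      }
      pick <- sample(idx, n_per_class)
      data.frame(row = ((pick - 1L) %% nrow(m)) + 1L,
                 col = ((pick - 1L) %/% nrow(m)) + 1L,
                 label = cls)
    })
    do.call(rbind, out)
  })
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts (positive class =
#'   contaminated).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Pixel-wise confusion counting
#'
#' Compares a predicted map against a ground-truth mask over all labeled
#' truth pixels (truth code 255 is excluded). Positive class is
#' contaminated (1).
#'
#' @param pred Predicted [label_mask()].
#' @param truth Ground-truth [label_mask()] of the same shape.
#' @return A [confusion_counts()].
#' @export
confusion <- function(pred, truth) {
  p <- unclass(pred); t <- unclass(truth)
  if (!identical(dim(p), dim(t))) stop("shape mismatch between pred and truth")
  keep <- t != 255L
  p <- p[keep]; t <- t[keep]
  if (any(p == 255L)) stop("predictions contain unlabeled pixels over labeled truth")
  confusion_counts(tp = sum(p == 1L & t == 1L),
                   tn = sum(p == 0L & t == 0L),
                   fp = sum(p == 1L & t == 0L),
                   fn = sum(p == 0L & t == 1L))
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN), precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F1 = harmonic mean of precision and recall.
#' Precision or recall with a zero denominator is reported as `NA` with a
#' flag rather than 0 or 1, so undefined folds do not silently bias CV
#' summaries.
#'
#' @param c A [confusion_counts()].
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (fractions in \[0, 1\] or `NA`), and
#'   `undefined` (character vector of flagged metrics).
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("empty-comparison error: all counts are zero")
  undefined <- character(0)
  precision <- if (c$tp + c$fp > 0) c$tp / (c$tp + c$fp) else {
    undefined <- c(undefined, "precision"); NA_real_
  }
  recall <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else {
    undefined <- c(undefined, "recall"); NA_real_
  }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    undefined <- c(undefined, "f1"); NA_real_
  }
  structure(list(accuracy = (c$tp + c$tn) / total, precision = precision,
                 recall = recall, f1 = f1, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.2f%%, precision %.4f, recall %.4f, F1 %.4f\n",
              100 * x$accuracy, x$precision, x$recall, x$f1))
  if (length(x$undefined)) {
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-class pixel fractions of a map
#'
#' @param map A [label_mask()].
#' @param include_unlabeled If `FALSE` (default), fractions are computed
#'   over labeled (non-255) pixels only; if `TRUE`, over all pixels with
#'   an additional `unlabeled` entry.
#' @return Named numeric vector of fractions (`clean`, `contaminated`,
#'   optionally `unlabeled`) summing to 1.
#' @export
class_fraction <- function(map, include_unlabeled = FALSE) {
  m <- unclass(map)
  if (include_unlabeled) {
    n <- length(m)
    c(clean = sum(m == 0L) / n, contaminated = sum(m == 1L) / n,
      unlabeled = sum(m == 255L) / n)
  } else {
    n <- sum(m != 255L)
    if (n == 0) stop("all pixels are unlabeled")
    c(clean = sum(m == 0L) / n, contaminated = sum(m == 1L) / n)
  }
}

ERROR_MAP_PALETTE <- c(TP = "blue", TN = "green", FP = "yellow", FN = "red",
                       unlabeled = "black")

#' Spatial error map
#'
#' Categorizes every pixel of a prediction against the truth: TP (rendered
#' blue), TN (green), FP (yellow), FN (red), unlabeled truth (black). The
#' category histogram equals [confusion()] on the same pair.
#'
#' @param pred Predicted [label_mask()].
#' @param truth Ground-truth [label_mask()] of the same shape.
#' @return An object of class `error_map`: list with `categories`
#'   (character matrix), `counts` (a [confusion_counts()]), and `palette`.
#' @seealso [write_error_map()]
#' @export
error_map <- function(pred, truth) {
  p <- unclass(pred); t <- unclass(truth)
  if (!identical(dim(p), dim(t))) stop("shape mismatch between pred and truth")
  cat_m <- matrix("unlabeled", nrow(p), ncol(p))
  cat_m[t == 1L & p == 1L] <- "TP"
  cat_m[t == 0L & p == 0L] <- "TN"
  cat_m[t == 0L & p == 1L] <- "FP"
  cat_m[t == 1L & p == 0L] <- "FN"
  structure(list(categories = cat_m, counts = confusion(pred, truth),
                 palette = ERROR_MAP_PALETTE), class = "error_map")
}

#' Write an error map (or class map) as a color PNG
#'
#' Error maps use the fixed palette blue/green/yellow/red/black for
#' TP/TN/FP/FN/unlabeled; class maps ([label_mask()]) use green for clean,
#' blue for contaminated, black for unlabeled.
#'
#' @param x An `error_map` or a [label_mask()].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_error_map <- function(x, path) {
  if (inherits(x, "label_mask")) {
    m <- unclass(x)
    cat_m <- matrix("unlabeled", nrow(m), ncol(m))
    cat_m[m == 0L] <- "TN"  # clean -> green
    cat_m[m == 1L] <- "TP"  # contaminated -> blue
    pal <- ERROR_MAP_PALETTE
  } else {
    stopifnot(inherits(x, "error_map"))
    cat_m <- x$categories
    pal <- x$palette
  }
  rgb_vals <- grDevices::col2rgb(pal[cat_m]) / 255
  img <- array(0, dim = c(nrow(cat_m), ncol(cat_m), 3))
  img[, , 1] <- matrix(rgb_vals[1, ], nrow(cat_m))
  img[, , 2] <- matrix(rgb_vals[2, ], nrow(cat_m))
  img[, , 3] <- matrix(rgb_vals[3, ], nrow(cat_m))
  png::writePNG(img, path)
  invisible(path)
}
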