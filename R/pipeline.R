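# End-to-end orchestration: simulate/load -> calibrate -> preprocess ->
# sparse PCA -> SVM -> whole-cube classification -> spatial evaluation.

#' Run configuration
#'
#' Bundles every parameter of an end-to-end run. Input is either a phantom
#' configuration (`phantom`) or paths to an ENVI cube plus white/dark
#' references and a ground-truth mask. Training spectra come from one
#' clean and one contaminated ROI; if ROIs are omitted, pure 30 x 30
#' windows are located automatically in the ground-truth mask.
#'
#' @param phantom A [phantom_config()], or `NULL` when reading from files.
#' @param cube_path,white_path,dark_path,truth_path Input paths (ignored
#'   when `phantom` is given). References are ENVI cubes; truth is a PNG
#'   mask.
#' @param roi_clean,roi_contaminated Optional [roi_spec()]s for training
#'   data.
#' @param roi_size Window side for automatic ROI search (default 30).
#' @param cutoff_nm,baseline_percentile,savgol_order,savgol_window
#'   Preprocessing parameters.
#' @param k,lambda Sparse PCA configuration (defaults 4, 0.5).
#' @param C SVM box constraint (default 1).
#' @param folds Cross-validation folds for the report (default 10).
#' @param erode_radius Ground-truth erosion radius before evaluation
#'   (default 1).
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = NULL, cube_path = NULL, white_path = NULL,
                       dark_path = NULL, truth_path = NULL,
                       roi_clean = NULL, roi_contaminated = NULL,
                       roi_size = 30, cutoff_nm = 480,
                       baseline_percentile = 10, savgol_order = 3,
                       savgol_window = 11, k = 4, lambda = 0.5, C = 1,
                       folds = 10, erode_radius = 1, seed = 1,
                       out_dir = NULL) {
  cfg <- list(phantom = phantom, cube_path = cube_path,
              white_path = white_path, dark_path = dark_path,
              truth_path = truth_path, roi_clean = roi_clean,
              roi_contaminated = roi_contaminated, roi_size = roi_size,
              cutoff_nm = cutoff_nm, baseline_percentile = baseline_percentile,
              savgol_order = savgol_order, savgol_window = savgol_window,
              k = k, lambda = lambda, C = C, folds = folds,
              erode_radius = erode_radius, seed = seed, out_dir = out_dir)
  if (is.null(phantom)) {
    paths <- list(cube_path, white_path, dark_path, truth_path)
    for (p in paths) {
      if (is.null(p) || !file.exists(p)) {
        stop(sprintf("configuration error: input path '%s' missing",
                     if (is.null(p)) "<null>" else p))
      }
    }
  }
  if (seed < 0 || seed != round(seed)) {
    stop("configuration error: seed must be a non-negative integer")
  }
  structure(cfg, class = "run_config")
}

# first fully pure roi_size x roi_size window of the given class,
# scanning row-major on a coarse stride; deterministic
.find_pure_roi <- function(truth, label, size) {
  m <- unclass(truth)
  for (stride in unique(c(max(1L, size %/% 3L), 1L))) {
    for (r in seq(1L, nrow(m) - size + 1L, by = stride)) {
      for (c in seq(1L, ncol(m) - size + 1L, by = stride)) {
        block <- m[r:(r + size - 1L), c:(c + size - 1L)]
        if (all(block == label)) {
          return(roi_spec(c(r, c), width = size, height = size, label = label,
                          origin_is_xy = FALSE))
        }
      }
    }
  }
  stop(sprintf("no pure %d x %d window of class %d found in the truth mask",
               size, size, label))
}

.log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

.load_inputs <- function(config) {
  if (!is.null(config$phantom)) {
    scene <- render_scene(config$phantom)
    list(cube = scene$cube, refs = scene_refs(scene), truth = scene$truth)
  } else {
    list(cube = read_envi_cube(config$cube_path),
         refs = reference_pair(read_envi_cube(config$white_path)$data,
                               read_envi_cube(config$dark_path)$data),
         truth = read_mask(config$truth_path))
  }
}

.run_core <- function(config, extractor = c("sparse", "dense"),
                      verbose = FALSE) {
  extractor <- match.arg(extractor)
  inputs <- .load_inputs(config)
  .log_stage(verbose, "load", "cube %s, %.1f%% of truth contaminated",
             paste(dim(inputs$cube$data), collapse = "x"),
             100 * mean(unclass(inputs$truth) == 1L))
  cal <- calibrate(inputs$cube, inputs$refs)

  roi_clean <- config$roi_clean
  roi_cont <- config$roi_contaminated
  if (is.null(roi_clean)) {
    roi_clean <- .find_pure_roi(inputs$truth, 0L, config$roi_size)
  }
  if (is.null(roi_cont)) {
    roi_cont <- .find_pure_roi(inputs$truth, 1L, config$roi_size)
  }
  train_raw <- rbind(extract_roi(cal, roi_clean)$values,
                     extract_roi(cal, roi_cont)$values)
  train_labels <- c(rep(0L, roi_clean$width * roi_clean$height),
                    rep(1L, roi_cont$width * roi_cont$height))
  train_m <- spectrum_matrix(train_raw, cal$grid, train_labels)
  .log_stage(verbose, "roi", "training spectra: %d clean + %d contaminated",
             sum(train_labels == 0L), sum(train_labels == 1L))

  pp <- preprocess_pipeline(train_m, cutoff_nm = config$cutoff_nm,
                            baseline_percentile = config$baseline_percentile,
                            savgol_order = config$savgol_order,
                            savgol_window = config$savgol_window)
  spca <- if (extractor == "sparse") {
    suppressWarnings(fit_sparse_pca(pp, k = config$k, lambda = config$lambda))
  } else {
    fit_standard_pca(pp, k = config$k)
  }
  .log_stage(verbose, "fit", "%s extractor, nonzero loadings: %s", extractor,
             paste(spca$nonzero_counts, collapse = ", "))
  svm <- train_svm(spca_transform(spca, pp), pp$labels, C = config$C,
                   seed = config$seed)
  cv <- crossval(pp, folds = config$folds, k = config$k,
                 lambda = if (extractor == "sparse") config$lambda else 0,
                 C = config$C, seed = config$seed)
  .log_stage(verbose, "cv", "mean accuracy %.4f", cv$mean[["accuracy"]])

  map <- classify_cube(cal, NULL, spca, svm, cutoff_nm = config$cutoff_nm,
                       baseline_percentile = config$baseline_percentile,
                       savgol_order = config$savgol_order,
                       savgol_window = config$savgol_window)
  truth_eval <- erode_mask(inputs$truth, config$erode_radius)
  cc <- confusion(map, truth_eval)
  mt <- metrics(cc)
  .log_stage(verbose, "evaluate", "pixel accuracy %.4f", mt$accuracy)

  list(extractor = extractor,
       spca = spca, svm = svm, map = map, truth = truth_eval,
       confusion = cc, metrics = mt,
       class_fractions = class_fraction(map),
       sparsity = sparsity_stats(spca),
       crossval = cv,
       rois = list(clean = roi_clean, contaminated = roi_cont))
}

.model_json <- function(spca, svm, config) {
  list(
    sparse_pca = list(lambda = spca$lambda, k = spca$n_components,
                      loadings = spca$loadings,
                      column_means = spca$column_means,
                      column_scales = spca$column_scales,
                      nonzero_counts = spca$nonzero_counts,
                      explained_variance = spca$explained_variance,
                      converged = spca$converged),
    svm = list(C = svm$C, kernel_scale = svm$kernel_scale,
               kernel_scale_policy = svm$kernel_scale_policy,
               n_per_class = svm$n_per_class),
    preprocessing = list(cutoff_nm = config$cutoff_nm,
                         baseline_percentile = config$baseline_percentile,
                         savgol_order = config$savgol_order,
                         savgol_window = config$savgol_window)
  )
}

#' Run the full pipeline
#'
#' Executes simulate/load, calibration, ROI harvesting, preprocessing,
#' sparse PCA, SVM training, cross-validation, whole-cube classification
#' and ground-truth evaluation. Deterministic for a given configuration
#' and seed. When `config$out_dir` is set, writes `metrics.json`,
#' `model.json`, `class_map.png`, `error_map.png` and `truth.png` there.
#'
#' @param config A [run_config()].
#' @param verbose Log one line per stage (default `FALSE`).
#' @return A run report list: fitted models, classification map,
#'   confusion counts, metrics, class fractions, sparsity report and CV
#'   summary.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  res <- .run_core(config, "sparse", verbose = verbose)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      metrics = list(accuracy = res$metrics$accuracy,
                     precision = res$metrics$precision,
                     recall = res$metrics$recall, f1 = res$metrics$f1),
      confusion = unclass(res$confusion),
      class_fractions = as.list(res$class_fractions),
      sparsity_overall_pct = res$sparsity$overall_pct,
      cv_mean = as.list(res$crossval$mean),
      seed = config$seed
    )
    jsonlite::write_json(report, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(.model_json(res$spca, res$svm, config),
                         file.path(config$out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    write_error_map(res$map, file.path(config$out_dir, "class_map.png"))
    write_error_map(error_map(res$map, res$truth),
                    file.path(config$out_dir, "error_map.png"))
    write_mask(res$truth, file.path(config$out_dir, "truth.png"))
  }
  res
}

#' Compare sparse against dense PCA features
#'
#' Runs the pipeline twice on identical inputs and protocol, once with the
#' adaptive soft-threshold sparse extractor and once with the dense PCA
#' baseline, and reports paired per-pixel metrics with a delta summary and
#' both sparsity tables.
#'
#' @param config A [run_config()].
#' @param verbose Log stage lines.
#' @return A list with `sparse`, `dense` (full run reports) and `delta`
#'   (sparse minus dense accuracy/precision/recall/f1).
#' @export
compare_baselines <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  sparse <- .run_core(config, "sparse", verbose = verbose)
  dense <- .run_core(config, "dense", verbose = verbose)
  delta <- vapply(c("accuracy", "precision", "recall", "f1"), function(nm) {
    sparse$metrics[[nm]] - dense$metrics[[nm]]
  }, numeric(1))
  list(sparse = sparse, dense = dense, delta = delta,
       sparsity = list(sparse = sparse$sparsity, dense = dense$sparsity))
}
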