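#' Seasonal features from raw Terra/Aqua coarse composites
#'
#' Convenience chain: merge the two sensors to an 8-day stream, screen the
#' reliability flags, remove residual outliers with STL, smooth with the
#' Savitzky-Golay filter and compute the 90 seasonal statistics.
#'
#' @param terra,aqua `coarse_series` objects.
#' @param half_window,poly_order Savitzky-Golay settings.
#' @param k_sd STL outlier threshold in robust standard deviations.
#' @param step_days Regular grid step in days.
#' @return A `seasonal_features` matrix.
#' @export
prepare_seasonal_features <- function(terra, aqua, half_window = 4L,
                                      poly_order = 2L, k_sd = 3,
                                      step_days = 8L) {
  merged <- merge_terra_aqua(terra, aqua)
  screened <- screen_reliability(merged)
  screened <- stl_outlier_removal(screened, step_days = step_days,
                                  k_sd = k_sd)
  smoothed <- savitzky_golay_smooth(screened, half_window = half_window,
                                    poly_order = poly_order,
                                    step_days = step_days)
  seasonal_statistics(smoothed)
}

# Stratified draw of training cells from the truth raster.
.truth_training_cells <- function(class_raster, n_per_class, seed) {
  with_seed(seed, unlist(lapply(unname(legend_classes()), function(cl) {
    cells <- which(class_raster == cl)
    if (length(cells) <= n_per_class) cells
    else cells[sample.int(length(cells), n_per_class)]
  }), use.names = FALSE))
}

#' Run the full synthetic mapping study once
#'
#' Generates a landscape, simulates fine and coarse observation streams,
#' builds the three composite predictor sets (single-date DOY-210, one-year
#' metrics, three-year epoch metrics), trains and assesses the land-cover
#' classifier on each, derives fractional training data from the best
#' (epoch) land-cover map, fits the per-type fraction forests on seasonal
#' coarse features, predicts wall-to-wall fractions and validates them
#' against the known true fractions.
#'
#' Fine reflectance is simulated only at the cells the study consumes
#' (classifier training cells, a map-evaluation sample, and the fine pixels
#' of the fraction-training blocks), which is exact and keeps memory and
#' runtime modest.
#'
#' @param seed Master seed; all internal seeds derive from it.
#' @param n_rows,n_cols,coarse_factor Landscape geometry.
#' @param years Fine acquisition years (epoch).
#' @param metrics_year Year used for the single-date and one-year sets.
#' @param n_train_per_class Classifier training cells per class.
#' @param n_map_eval Map-evaluation sample size (acts as the map for the
#'   stratified accuracy assessment).
#' @param n_assess_per_class Accuracy-assessment samples per mapped class.
#' @param n_fraction_train Target number of fraction-training blocks.
#' @param n_trees Random-forest tree count for both tasks.
#' @param n_per_stratum Validation samples per stratum.
#' @return List with `oa` (named OA per composite type), `error_matrices`,
#'   `validation` (a `validation_report` against the true fractions),
#'   `predicted` and `truth_fractions` maps.
#' @export
run_synthetic_study <- function(seed = 1L,
                                n_rows = 512L, n_cols = 512L,
                                coarse_factor = 8L,
                                years = 2009:2011, metrics_year = 2010L,
                                n_train_per_class = 500L,
                                n_map_eval = 14000L,
                                n_assess_per_class = 300L,
                                n_fraction_train = 300L,
                                n_trees = 1000L,
                                n_per_stratum = 1000L) {
  spec <- landscape_spec(n_rows, n_cols, coarse_factor = coarse_factor,
                         seed = seed)
  truth <- generate_landscape(spec)
  cal <- acquisition_calendar(years, seed = seed + 101L)

  # cells consumed by the study
  train_cells <- .truth_training_cells(truth$class_raster,
                                       n_train_per_class, seed + 11L)
  cdims <- c(n_rows %/% coarse_factor, n_cols %/% coarse_factor)
  floc <- sample_training_pixels(cdims, pixel_size = 30 * coarse_factor,
                                 n_target = n_fraction_train,
                                 min_dist = 1000, seed = seed + 12L)
  block_cells <- unlist(lapply(seq_len(nrow(floc)), function(i) {
    rr <- (floc$row[i] - 1L) * coarse_factor + seq_len(coarse_factor)
    cc <- (floc$col[i] - 1L) * coarse_factor + seq_len(coarse_factor)
    as.vector(outer(rr, (cc - 1L) * n_rows, `+`))
  }))
  eval_cells <- with_seed(seed + 13L,
    sample.int(n_rows * n_cols, min(n_map_eval, n_rows * n_cols)))
  pixels <- sort(unique(c(train_cells, eval_cells, block_cells)))
  stack <- simulate_fine_series(truth, cal, pixels = pixels,
                                seed = seed + 102L)

  feats <- list(
    single_date = single_date_composite(stack, 210L, metrics_year),
    metrics_1yr = temporal_metrics(stack, metrics_year),
    metrics_epoch = temporal_metrics(stack, years))

  i_train <- match(train_cells, pixels)
  i_eval <- match(eval_cells, pixels)
  params <- rf_params(n_trees = n_trees, seed = seed + 21L)
  oa <- c(); ems <- list(); models <- list()
  for (tp in names(feats)) {
    f <- feats[[tp]]
    xt <- unclass(f)[i_train, , drop = FALSE]
    keep <- stats::complete.cases(xt)
    model <- train_classifier(xt[keep, , drop = FALSE],
                              truth$class_raster[train_cells][keep], params)
    models[[tp]] <- model
    pred_eval <- classify(model, structure(
      unclass(f)[i_eval, , drop = FALSE],
      class = class(f), dims = NULL))
    samp <- stratified_reference_sample(pred_eval, n_assess_per_class,
                                        seed = seed + 31L)
    em <- error_matrix(pred_eval[samp$cell],
                       truth$class_raster[eval_cells][samp$cell])
    ems[[tp]] <- em
    oa[tp] <- em$overall_accuracy
  }

  # land-cover reference for fraction training: epoch map at block cells
  i_block <- match(block_cells, pixels)
  lc_block <- classify(models$metrics_epoch, structure(
    unclass(feats$metrics_epoch)[i_block, , drop = FALSE],
    class = class(feats$metrics_epoch), dims = NULL))
  lc_full <- matrix(NA_integer_, n_rows, n_cols)
  lc_full[block_cells] <- lc_block
  ref_fr <- compute_reference_fractions(lc_full, coarse_factor)

  co <- simulate_coarse_series(truth, seed = seed + 103L)
  sf <- prepare_seasonal_features(co$terra, co$aqua)
  xf <- unclass(sf)[floc$cell, , drop = FALSE]
  fr_train <- data.frame(deciduous = as.vector(ref_fr$deciduous)[floc$cell],
                         evergreen = as.vector(ref_fr$evergreen)[floc$cell],
                         mixed = as.vector(ref_fr$mixed)[floc$cell])
  ok <- stats::complete.cases(xf) & stats::complete.cases(fr_train)
  fmods <- train_fraction_models(xf[ok, , drop = FALSE], fr_train[ok, ],
                                 rf_params(n_trees = n_trees,
                                           seed = seed + 41L))
  pred <- predict_fractions(fmods, sf)
  tf <- true_fractions(truth)
  pred <- lapply(pred, function(m) matrix(m, cdims[1], cdims[2]))
  class(pred) <- "fraction_map"
  vrep <- validate_fractions(pred, tf, n_per_stratum = n_per_stratum,
                             seed = seed + 51L)
  list(oa = oa, error_matrices = ems, validation = vrep,
       predicted = pred, truth_fractions = tf,
       n_fraction_train = sum(ok))
}

#' Agreement between noisy tree-cover map pairs across scales
#'
#' Builds a reference tree-cover percent map from a synthetic landscape's
#' true overall forest fraction, perturbs it with i.i.d. pixel noise, and
#' reports Pearson r and OLS slope at each aggregation factor — emulating
#' the comparison of independently produced cover maps whose agreement
#' improves as geolocation-scale noise averages out in larger blocks.
#'
#' @param seed Seed for landscape and noise.
#' @param n_rows,n_cols,coarse_factor Landscape geometry (native comparison
#'   scale is the coarse grid).
#' @param noise_sd Noise sd in percent cover.
#' @param factors Aggregation factors.
#' @return An `agreement_report`.
#' @export
agreement_scaling_experiment <- function(seed = 1L, n_rows = 800L,
                                         n_cols = 800L, coarse_factor = 4L,
                                         noise_sd = 15,
                                         factors = c(1L, 4L, 20L)) {
  spec <- landscape_spec(n_rows, n_cols, coarse_factor = coarse_factor,
                         patch_scale = 24, seed = seed)
  truth <- generate_landscape(spec)
  mapA <- 100 * true_fractions(truth)$overall
  mapB <- with_seed(seed + 1L,
    pmin(pmax(mapA + rnorm(length(mapA), sd = noise_sd), 0), 100))
  mapB <- matrix(mapB, nrow(mapA), ncol(mapA))
  agreement(mapA, mapB, factors = factors)
}
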