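#' Sample coarse training pixels with a minimum-distance constraint
#'
#' Greedy random thinning: coarse cells are visited in random order and a
#' cell is accepted when its centre lies at least `min_dist` metres from
#' every previously accepted centre (default 1000 m, guarding against
#' spatial autocorrelation between neighbouring samples). Stops at
#' `n_target` accepted cells or exhaustion.
#'
#' @param dims Coarse grid dimensions `c(rows, cols)`.
#' @param pixel_size Coarse pixel edge length in metres.
#' @param n_target Desired number of samples.
#' @param min_dist Minimum centre-to-centre distance in metres.
#' @param seed Seed for the visiting order.
#' @return Data frame with `cell` (column-major index), `row`, `col`.
#' @export
sample_training_pixels <- function(dims, pixel_size = 240, n_target = 500L,
                                   min_dist = 1000, seed = 1L) {
  stopifnot(min_dist >= 0)
  n <- prod(dims)
  cand <- with_seed(seed, sample.int(n))
  if (min_dist <= 0) {
    take <- cand[seq_len(min(n_target, n))]
  } else {
    r_acc <- numeric(0); c_acc <- numeric(0); take <- integer(0)
    d2 <- (min_dist / pixel_size)^2
    for (cell in cand) {
      ri <- (cell - 1L) %% dims[1] + 1L
      ci <- (cell - 1L) %/% dims[1] + 1L
      if (length(take) == 0L ||
          min((r_acc - ri)^2 + (c_acc - ci)^2) >= d2) {
        take <- c(take, cell); r_acc <- c(r_acc, ri); c_acc <- c(c_acc, ci)
        if (length(take) >= n_target) break
      }
    }
    if (length(take) < n_target)
      message("minimum-distance sampler accepted ", length(take), " of ",
              n_target, " requested samples")
  }
  data.frame(cell = take,
             row = (take - 1L) %% dims[1] + 1L,
             col = (take - 1L) %/% dims[1] + 1L)
}

#' Reference forest fractions from a fine land-cover map
#'
#' Per coarse cell, the proportion of fine pixels mapped as each forest
#' type. Missing fine pixels are excluded from the denominator; cells more
#' than half missing are dropped (fraction set `NA`).
#'
#' @param landcover Integer legend codes on the fine grid (matrix, or a
#'   vector with `dims` supplied), `NA` = missing.
#' @param coarse_factor Fine pixels per coarse pixel edge.
#' @param dims Fine-grid dimensions when `landcover` is a vector.
#' @param max_missing Maximum tolerated missing share per cell.
#' @return A `fraction_map` on the coarse grid (deciduous, evergreen,
#'   mixed, overall).
#' @export
compute_reference_fractions <- function(landcover, coarse_factor,
                                        dims = NULL, max_missing = 0.5) {
  if (is.null(dim(landcover))) {
    stopifnot(!is.null(dims))
    landcover <- matrix(landcover, dims[1], dims[2])
  }
  m <- landcover
  miss <- is.na(m)
  m[miss] <- legend_classes()["water"]  # placeholder, excluded below
  arr <- block_class_fractions(m, coarse_factor)
  f <- coarse_factor^2
  missing_frac <- block_class_fractions(miss + 0L + 1L, coarse_factor)
  # classes coded 1 (clear) and 2 (missing) above; share of missing:
  dd <- dim(arr)[1:2]
  pm <- matrix(missing_frac[, , 2], dd[1], dd[2])
  valid <- 1 - pm
  mk <- function(cl) {
    x <- matrix(arr[, , cl], dd[1], dd[2])
    out <- ifelse(valid > 0, x / valid, NA_real_)
    out[pm > max_missing] <- NA_real_
    out
  }
  fm <- list(deciduous = mk("deciduous"), evergreen = mk("evergreen"),
             mixed = mk("mixed"))
  fm$overall <- fm$deciduous + fm$evergreen + fm$mixed
  structure(fm, class = "fraction_map")
}

#' Train per-type fraction regression forests
#'
#' Fits three independent random-forest regressions — deciduous, evergreen,
#' mixed — of reference cover fraction on the 90 seasonal features. Each
#' model gets its own derived seed, so the models are independent of one
#' another's training rows.
#'
#' @param features Numeric matrix (samples x features) with column names.
#' @param fractions Data frame or list with numeric `deciduous`,
#'   `evergreen`, `mixed` in \[0, 1\].
#' @param params An [rf_params()].
#' @return A `fraction_models` object (list of three fits + schema).
#' @export
train_fraction_models <- function(features, fractions,
                                  params = rf_params()) {
  features <- unclass(features)
  if (nrow(features) == 0L) stop("empty training set")
  if (anyNA(features)) stop("training features contain missing values")
  types <- c("deciduous", "evergreen", "mixed")
  models <- lapply(seq_along(types), function(i) {
    y <- fractions[[types[i]]]
    stopifnot(length(y) == nrow(features), all(y >= 0 & y <= 1))
    if (length(unique(y)) == 1L) return(list(constant = y[1]))
    with_seed(params$seed + i,
      randomForest::randomForest(x = features, y = y,
                                 ntree = params$n_trees,
                                 mtry = mtry_sqrt(ncol(features)),
                                 nodesize = params$min_node_size))
  })
  names(models) <- types
  structure(list(models = models, features = colnames(features),
                 params = params),
            class = "fraction_models")
}

#' Predict wall-to-wall forest-cover fractions
#'
#' Applies the three per-type forests; type predictions are clipped to
#' \[0, 1\] and overall forest cover is their sum, clipped to \[0, 1\].
#' Pixels with missing features are missing in the output.
#'
#' @param models A `fraction_models` object.
#' @param features A `seasonal_features` matrix (or any matrix matching the
#'   training schema).
#' @return A `fraction_map`; matrices when the feature table carries grid
#'   dims, otherwise vectors.
#' @export
predict_fractions <- function(models, features) {
  x <- unclass(features)
  if (!identical(colnames(x), models$features))
    stop("feature schema does not match the trained models")
  ok <- !missing_pixels(x)
  shape <- function(v) {
    d <- attr(features, "dims")
    if (!is.null(d)) matrix(v, d[1], d[2]) else v
  }
  preds <- lapply(models$models, function(m) {
    p <- rep(NA_real_, nrow(x))
    if (any(ok)) {
      p[ok] <- if (!is.null(m$constant)) m$constant
               else predict(m, x[ok, , drop = FALSE])
    }
    pmin(pmax(p, 0), 1)
  })
  fm <- list(deciduous = shape(preds$deciduous),
             evergreen = shape(preds$evergreen),
             mixed = shape(preds$mixed))
  fm$overall <- pmin(pmax(fm$deciduous + fm$evergreen + fm$mixed, 0), 1)
  structure(fm, class = "fraction_map")
}

#' Normalized root-mean-square error
#'
#' `NRMSE = sqrt(sum((P_i - R_i)^2) / n) / mean(R)`: the RMSE between
#' predictions and reference divided by the mean reference value. Undefined
#' (returned as `NA`) when the mean reference is zero.
#'
#' @param predicted,reference Equal-length numeric vectors.
#' @return A single number, or `NA` when `mean(reference) == 0`.
#' @export
nrmse <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference), length(reference) > 0)
  rbar <- mean(reference)
  if (rbar == 0) return(NA_real_)
  sqrt(mean((predicted - reference)^2)) / rbar
}

#' Validate fraction maps with a two-stratum sample
#'
#' Strata are defined on the predicted map: cells with predicted overall
#' forest cover > 0 (forest) and exactly 0 (non-forest). Up to
#' `n_per_stratum` cells are drawn from each stratum without replacement;
#' NRMSE and Pearson r are computed per target (three types and overall)
#' over the pooled sample.
#'
#' @param predicted,reference Aligned `fraction_map` objects.
#' @param n_per_stratum Samples per stratum (default 1000).
#' @param seed Seed for the draw.
#' @return A `validation_report`: data frame with target, nrmse, pearson_r,
#'   n; attribute `cells` holds the sampled indices.
#' @export
validate_fractions <- function(predicted, reference,
                               n_per_stratum = 1000L, seed = 1L) {
  po <- as.vector(predicted$overall)
  usable <- which(!is.na(po) & !is.na(as.vector(reference$overall)))
  strata <- list(forest = usable[po[usable] > 0],
                 nonforest = usable[po[usable] == 0])
  cells <- with_seed(seed, unlist(lapply(strata, function(s) {
    if (length(s) <= n_per_stratum) s
    else s[sample.int(length(s), n_per_stratum)]
  }), use.names = FALSE))
  targets <- c("deciduous", "evergreen", "mixed", "overall")
  rep_df <- do.call(rbind, lapply(targets, function(tg) {
    p <- as.vector(predicted[[tg]])[cells]
    r <- as.vector(reference[[tg]])[cells]
    data.frame(target = tg, nrmse = nrmse(p, r),
               pearson_r = if (sd(p) > 0 && sd(r) > 0) cor(p, r)
                           else NA_real_,
               n = length(cells))
  }))
  structure(rep_df, class = c("validation_report", "data.frame"),
            cells = cells)
}
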