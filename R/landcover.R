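#' Random-forest hyperparameters
#'
#' Defaults follow common practice for land-cover work: 1000 trees, terminal
#' node size 10, and mtry equal to the floor of the square root of the
#' number of predictors (computed at fit time).
#'
#' @param n_trees Number of trees.
#' @param min_node_size Minimum terminal node size.
#' @param seed Seed used when fitting.
#' @return An `rf_params` list.
#' @export
rf_params <- function(n_trees = 1000L, min_node_size = 10L, seed = 1L) {
  stopifnot(n_trees >= 1L, min_node_size >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "rf_params")
}

#' mtry from the square-root rule
#' @param p Number of predictors.
#' @return `floor(sqrt(p))`, at least 1.
#' @export
mtry_sqrt <- function(p) max(1L, as.integer(floor(sqrt(p))))

#' Train the land-cover classifier
#'
#' Fits a random forest on composite features with integer legend labels.
#' Feature vectors must be complete; a training set with a single class
#' yields a constant classifier (that class everywhere).
#'
#' @param features Numeric matrix (pixels x features) with column names.
#' @param labels Integer legend codes, one per row of `features`.
#' @param params An [rf_params()].
#' @return A `landcover_model`.
#' @export
train_classifier <- function(features, labels, params = rf_params()) {
  features <- unclass(features)
  if (nrow(features) == 0L) stop("empty training set")
  if (anyNA(features)) stop("training features contain missing values")
  stopifnot(nrow(features) == length(labels))
  labels <- as.integer(labels)
  lv <- sort(unique(labels))
  if (length(lv) == 1L) {
    model <- structure(list(constant = lv, features = colnames(features),
                            params = params),
                       class = "landcover_model")
    return(model)
  }
  y <- factor(labels, levels = lv)
  rf <- with_seed(params$seed,
    randomForest::randomForest(x = features, y = y,
                               ntree = params$n_trees,
                               mtry = mtry_sqrt(ncol(features)),
                               nodesize = params$min_node_size))
  structure(list(rf = rf, levels = lv, features = colnames(features),
                 params = params),
            class = "landcover_model")
}

#' Classify composite features into a land-cover map
#'
#' Per-pixel class is the majority of tree votes; exact vote ties are
#' resolved deterministically in favour of the lowest legend code. Pixels
#' with missing features get `NA`.
#'
#' @param model A `landcover_model`.
#' @param features A `composite_features` matrix or plain numeric matrix
#'   whose columns match the training schema.
#' @return Integer vector of legend codes (`NA` = missing), with attribute
#'   `dims` when the input carries one.
#' @export
classify <- function(model, features) {
  x <- unclass(features)
  if (!identical(colnames(x), model$features))
    stop("feature schema does not match the trained model")
  out <- rep(NA_integer_, nrow(x))
  ok <- !missing_pixels(x)
  if (any(ok)) {
    if (!is.null(model$constant)) {
      out[ok] <- model$constant
    } else {
      votes <- predict(model$rf, x[ok, , drop = FALSE], type = "vote")
      out[ok] <- .majority_vote(votes, model$levels)
    }
  }
  attr(out, "dims") <- attr(features, "dims")
  out
}

# Majority of tree votes; exact ties go to the lowest legend code.
# `votes` columns must be ordered by ascending code, matching `levels`.
.majority_vote <- function(votes, levels) {
  levels[max.col(votes, ties.method = "first")]
}

#' Disproportionate stratified reference sample
#'
#' Draws up to `n_per_class` pixels per mapped class, without replacement,
#' regardless of class area — securing validation samples for rare classes.
#' Classes smaller than `n_per_class` are exhausted; classes absent from the
#' map produce a warning and zero samples.
#'
#' @param map Integer legend codes (vector or matrix), `NA` = missing.
#' @param n_per_class Samples per mapped class (default 300).
#' @param seed Seed for the draw.
#' @param classes Legend codes expected on the map.
#' @return Data frame with columns `cell` (index into `map`) and
#'   `map_class`.
#' @export
stratified_reference_sample <- function(map, n_per_class = 300L, seed = 1L,
                                        classes = legend_classes()) {
  m <- as.integer(map)
  res <- with_seed(seed, lapply(unname(classes), function(cl) {
    cells <- which(!is.na(m) & m == cl)
    if (length(cells) == 0L) {
      warning("class ", cl, " absent from the map; zero samples")
      return(NULL)
    }
    take <- if (length(cells) <= n_per_class) cells
            else cells[sample.int(length(cells), n_per_class)]
    data.frame(cell = take, map_class = cl)
  }))
  do.call(rbind, res)
}

#' Error matrix and accuracy summaries
#'
#' Square count table of mapped versus reference class with overall accuracy
#' (trace over total), per-class commission error (1 - user's accuracy) and
#' omission error (1 - producer's accuracy). When mapped-class area
#' proportions are supplied, an area-weighted overall accuracy is reported
#' alongside the raw sample OA (equal-allocation stratified samples
#' over-weight rare classes in the raw figure).
#'
#' @param predicted,reference Equal-length vectors of legend codes.
#' @param classes Legend codes defining the table order.
#' @param map_proportions Optional named area proportions of the mapped
#'   classes (summing to 1) for area-weighted OA.
#' @return An `error_matrix` object.
#' @export
error_matrix <- function(predicted, reference, classes = legend_classes(),
                         map_proportions = NULL) {
  if (length(predicted) == 0L) stop("empty input")
  stopifnot(length(predicted) == length(reference))
  cl <- unname(classes)
  counts <- table(factor(predicted, levels = cl),
                  factor(reference, levels = cl))
  dimnames(counts) <- list(map = cl, reference = cl)
  n <- sum(counts)
  diag_c <- diag(counts)
  row_t <- rowSums(counts); col_t <- colSums(counts)
  commission <- ifelse(row_t > 0, 1 - diag_c / row_t, NA_real_)
  omission <- ifelse(col_t > 0, 1 - diag_c / col_t, NA_real_)
  oa_w <- NULL
  if (!is.null(map_proportions)) {
    w <- map_proportions[as.character(cl)]
    ua <- ifelse(row_t > 0, diag_c / row_t, 0)
    oa_w <- sum(w * ua, na.rm = TRUE)
  }
  structure(list(counts = unclass(counts), overall_accuracy = sum(diag_c) / n,
                 commission = commission, omission = omission, n = n,
                 area_weighted_oa = oa_w),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("Error matrix (", x$n, " samples)\n", sep = "")
  print(x$counts)
  cat(sprintf("Overall accuracy: %.4f\n", x$overall_accuracy))
  if (!is.null(x$area_weighted_oa))
    cat(sprintf("Area-weighted OA: %.4f\n", x$area_weighted_oa))
  invisible(x)
}
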