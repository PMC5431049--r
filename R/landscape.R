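#' Specify a synthetic landscape
#'
#' Defines the geometry and class composition of a synthetic scene: a fine
#' grid (default 30 m pixels) that nests exactly into a coarse grid of
#' `coarse_factor` x `coarse_factor` blocks (default 8, i.e. 240 m coarse
#' pixels, so that fine pixels tile coarse pixels without resampling
#' ambiguity).
#'
#' @param n_rows,n_cols Fine-grid dimensions in pixels; each must be divisible
#'   by `coarse_factor`.
#' @param fine_pixel_size Fine pixel edge length in metres.
#' @param coarse_factor Integer block size of the coarse grid (>= 2).
#' @param class_weights Target area proportion per legend class, in the order
#'   of [legend_classes()]; non-negative, summing to 1.
#' @param patch_scale Characteristic patch diameter in fine pixels; used as
#'   the smoothing sigma of the random field behind the class map.
#' @param seed Integer seed controlling landscape realisation.
#' @return A `landscape_spec` object (list).
#' @export
landscape_spec <- function(n_rows = 512L, n_cols = 512L,
                           fine_pixel_size = 30,
                           coarse_factor = 8L,
                           class_weights = c(0.10, 0.08, 0.07, 0.08,
                                             0.30, 0.27, 0.10),
                           patch_scale = 12,
                           seed = 1L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  coarse_factor <- as.integer(coarse_factor)
  if (coarse_factor < 2L)
    stop("coarse_factor must be >= 2")
  if (n_rows %% coarse_factor != 0L || n_cols %% coarse_factor != 0L)
    stop("n_rows and n_cols must be divisible by coarse_factor")
  if (length(class_weights) != length(legend_classes()))
    stop("class_weights must have one entry per legend class")
  if (any(class_weights < 0) || sum(class_weights) <= 0)
    stop("class_weights must be non-negative with positive sum")
  class_weights <- class_weights / sum(class_weights)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 fine_pixel_size = fine_pixel_size,
                 coarse_factor = coarse_factor,
                 class_list = names(legend_classes()),
                 class_weights = class_weights,
                 patch_scale = patch_scale,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

# Per-class seasonal timing shared by all signals of that class.
.class_timing <- function() {
  data.frame(
    class  = names(legend_classes()),
    green  = c(125, 110, 120, 115,  80, 0, 0),
    sen    = c(285, 300, 290, 300, 175, 0, 0),
    steep  = c(0.10, 0.05, 0.08, 0.08, 0.10, 0.1, 0.1)
  )
}

#' Default class/signal phenology model
#'
#' Double-logistic seasonal curves, one per class and signal:
#' `value(doy) = base + amp * (plogis(k (doy - green)) - plogis(k (doy - sen)))`.
#' Fine signals are the six optical reflectance bands (blue, green, red, NIR,
#' SWIR1, SWIR2); coarse signals are NDVI, EVI and four reflectance bands.
#' Deciduous forest has the largest NDVI/NIR amplitude, evergreen the
#' smallest among forests; herbaceous land greens up and senesces early
#' (dryland spring flush), so it matches forest poorly over the season but
#' resembles barren land in mid-summer. These overlaps are what make
#' single-date composites genuinely harder than temporal metrics.
#'
#' @param fine_noise_sd Observation noise sd for fine reflectance bands.
#' @param coarse_index_noise_sd,coarse_band_noise_sd Noise sd for coarse
#'   vegetation indices and reflectance bands.
#' @return A `phenology_model`: data.frame with columns domain, class,
#'   signal, base, amp, green, sen, steep, noise_sd.
#' @export
default_phenology <- function(fine_noise_sd = 0.03,
                              coarse_index_noise_sd = 0.02,
                              coarse_band_noise_sd = 0.01) {
  cls <- names(legend_classes())
  fine_bands <- c("blue", "green", "red", "nir", "swir1", "swir2")
  coarse_sigs <- c("ndvi", "evi", "blue", "red", "nir", "swir")
  # base reflectance per class (rows) and band (cols)
  fb <- rbind(
    deciduous  = c(0.040, 0.060, 0.050, 0.220, 0.180, 0.100),
    evergreen  = c(0.030, 0.050, 0.040, 0.320, 0.140, 0.070),
    mixed      = c(0.035, 0.055, 0.045, 0.270, 0.160, 0.085),
    wetland    = c(0.050, 0.070, 0.060, 0.240, 0.150, 0.070),
    herbaceous = c(0.060, 0.090, 0.100, 0.200, 0.250, 0.180),
    barren     = c(0.070, 0.100, 0.120, 0.220, 0.280, 0.220),
    water      = c(0.050, 0.040, 0.030, 0.020, 0.010, 0.010))
  fa <- rbind(
    deciduous  = c(0.000,  0.020, -0.020, 0.260,  0.060,  0.020),
    evergreen  = c(0.000,  0.010, -0.010, 0.060,  0.020,  0.010),
    mixed      = c(0.000,  0.015, -0.015, 0.160,  0.040,  0.015),
    herbaceous = c(0.000,  0.030, -0.050, 0.220, -0.030, -0.040),
    wetland    = c(0.000,  0.020, -0.020, 0.240,  0.030,  0.010),
    barren     = c(0, 0, 0, 0, 0, 0),
    water      = c(0, 0, 0, 0, 0, 0))[cls, , drop = FALSE]
  cb <- rbind(
    deciduous  = c( 0.15, 0.10, 0.040, 0.050, 0.220, 0.140),
    evergreen  = c( 0.55, 0.35, 0.030, 0.040, 0.320, 0.100),
    mixed      = c( 0.35, 0.22, 0.035, 0.045, 0.270, 0.120),
    wetland    = c( 0.20, 0.12, 0.050, 0.060, 0.240, 0.110),
    herbaceous = c( 0.12, 0.08, 0.060, 0.100, 0.200, 0.200),
    barren     = c( 0.08, 0.05, 0.070, 0.120, 0.220, 0.280),
    water      = c(-0.05, -0.02, 0.050, 0.030, 0.020, 0.010))
  ca <- rbind(
    deciduous  = c(0.55, 0.35, 0.000, -0.020, 0.260,  0.040),
    evergreen  = c(0.15, 0.10, 0.000, -0.010, 0.060,  0.020),
    mixed      = c(0.35, 0.22, 0.000, -0.015, 0.160,  0.030),
    wetland    = c(0.45, 0.30, 0.000, -0.020, 0.240,  0.020),
    herbaceous = c(0.40, 0.25, 0.000, -0.050, 0.220, -0.030),
    barren     = c(0, 0, 0, 0, 0, 0),
    water      = c(0, 0, 0, 0, 0, 0))
  tim <- .class_timing()
  mk <- function(domain, signals, base, amp, noise) {
    g <- expand.grid(class = cls, signal = signals,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(g$class, rownames(base)); j <- match(g$signal, signals)
    k <- match(g$class, tim$class)
    data.frame(domain = domain, class = g$class, signal = g$signal,
               base = base[cbind(i, j)], amp = amp[cbind(i, j)],
               green = tim$green[k], sen = tim$sen[k], steep = tim$steep[k],
               noise_sd = noise[j], stringsAsFactors = FALSE)
  }
  ph <- rbind(
    mk("fine", fine_bands, fb, fa, rep(fine_noise_sd, 6)),
    mk("coarse", coarse_sigs, cb, ca,
       c(coarse_index_noise_sd, coarse_index_noise_sd,
         rep(coarse_band_noise_sd, 4))))
  class(ph) <- c("phenology_model", "data.frame")
  ph
}

#' Evaluate phenology curves
#'
#' @param phenology A `phenology_model`.
#' @param domain `"fine"` or `"coarse"`.
#' @param signal Signal name within the domain.
#' @param doy Vector of day-of-year values (1-366).
#' @return Matrix `length(doy)` x n_classes of noiseless signal values,
#'   columns in legend order.
#' @export
phenology_curve <- function(phenology, domain, signal, doy) {
  rows <- phenology[phenology$domain == domain & phenology$signal == signal, ]
  rows <- rows[match(names(legend_classes()), rows$class), ]
  if (nrow(rows) != length(legend_classes()) || anyNA(rows$base))
    stop("phenology model lacks entries for ", domain, "/", signal)
  out <- vapply(seq_len(nrow(rows)), function(i) {
    s <- stats::plogis(rows$steep[i] * (doy - rows$green[i])) -
      stats::plogis(rows$steep[i] * (doy - rows$sen[i]))
    rows$base[i] + rows$amp[i] * s
  }, numeric(length(doy)))
  out <- matrix(out, nrow = length(doy))
  colnames(out) <- rows$class
  lo <- if (domain == "coarse") -1 else 0
  pmin(pmax(out, lo), 1)
}

#' Generate a ground-truth landscape
#'
#' Draws a patchy categorical class map by quantile-slicing a smoothed
#' Gaussian random field: white noise is smoothed with sigma = `patch_scale`,
#' rank-transformed to uniform, and cut at the cumulative class weights, so
#' realised class proportions track the targets closely while patches have a
#' controllable characteristic size.
#'
#' @param spec A [landscape_spec()].
#' @param phenology A `phenology_model`; defaults to [default_phenology()].
#' @return A `ground_truth_landscape`: list with `class_raster` (integer
#'   matrix of legend codes), `phenology`, and `spec`.
#' @export
generate_landscape <- function(spec, phenology = default_phenology()) {
  stopifnot(inherits(spec, "landscape_spec"))
  w <- spec$class_weights
  if (sum(w) <= 0) stop("class weights are zero everywhere")
  cls <- with_seed(spec$seed, {
    z <- matrix(rnorm(spec$n_rows * spec$n_cols), spec$n_rows, spec$n_cols)
    f <- gauss_smooth(z, spec$patch_scale)
    u <- (rank(f, ties.method = "first") - 0.5) / length(f)
    matrix(findInterval(u, cumsum(w), left.open = TRUE) + 1L,
           spec$n_rows, spec$n_cols)
  })
  structure(list(class_raster = cls, phenology = phenology, spec = spec),
            class = "ground_truth_landscape")
}

# Per-coarse-block fractions of every legend class.
# Returns array [coarse_rows, coarse_cols, n_classes].
block_class_fractions <- function(class_raster, factor) {
  nr <- nrow(class_raster); nc <- ncol(class_raster)
  if (nr %% factor != 0 || nc %% factor != 0)
    stop("fine grid does not nest in coarse grid")
  cr <- nr %/% factor; cc <- nc %/% factor
  br <- (row(class_raster) - 1L) %/% factor
  bc <- (col(class_raster) - 1L) %/% factor
  block <- br + cr * bc  # 0-based block id, column-major over coarse grid
  k <- length(legend_classes())
  counts <- tabulate(block * k + class_raster, nbins = cr * cc * k)
  arr <- aperm(array(counts, dim = c(k, cr, cc)), c(2, 3, 1)) / factor^2
  dimnames(arr) <- list(NULL, NULL, names(legend_classes()))
  arr
}

#' True sub-pixel forest fractions of a landscape
#'
#' Counts fine pixels of each forest class within every coarse block and
#' divides by the block size; overall forest is the sum of the three types.
#'
#' @param truth A `ground_truth_landscape`.
#' @return A `fraction_map`: list of matrices `deciduous`, `evergreen`,
#'   `mixed`, `overall` on the coarse grid, values in \[0, 1\].
#' @export
true_fractions <- function(truth) {
  arr <- block_class_fractions(truth$class_raster, truth$spec$coarse_factor)
  sl <- function(k) matrix(arr[, , k], dim(arr)[1], dim(arr)[2])
  fm <- list(deciduous = sl("deciduous"), evergreen = sl("evergreen"),
             mixed = sl("mixed"))
  fm$overall <- fm$deciduous + fm$evergreen + fm$mixed
  structure(fm, class = "fraction_map")
}
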