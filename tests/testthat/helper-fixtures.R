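# Small hand-built objects mirroring the package's container layouts.

# A fine stack with fully controlled values: `values` is pixels x bands x
# acquisitions; `clear` pixels x acquisitions; `doy`/`year` per acquisition.
make_stack <- function(values, clear, doy, year, slc_off = FALSE,
                       bands = NULL) {
  np <- dim(values)[1]; nb <- dim(values)[2]; na <- dim(values)[3]
  if (is.null(bands)) bands <- paste0("b", seq_len(nb))
  stopifnot(nrow(clear) == np, ncol(clear) == na, length(doy) == na)
  year <- rep_len(year, na)
  cal <- data.frame(date = as.Date(paste0(year, "-01-01")) + doy - 1L,
                    year = year, doy = doy,
                    sensor = "TM", slc_off = rep_len(slc_off, na),
                    cloud_fraction = 0)
  structure(list(values = values, clear = clear, calendar = cal,
                 pixels = NULL, dims = c(np, 1L), bands = bands),
            class = "fine_series_stack")
}

# Single-band-per-signal coarse series with explicit doy/flag matrices.
make_coarse <- function(values, doy, flag = NULL, signals = NULL,
                        source = "terra", dims = NULL) {
  np <- dim(values)[1]; ns <- dim(values)[2]; nobs <- dim(values)[3]
  if (is.null(flag)) flag <- matrix(0L, np, nobs)
  if (is.null(signals)) signals <- paste0("s", seq_len(ns))
  if (is.null(dims)) dims <- c(np, 1L)
  periods <- data.frame(year = 2010L,
                        start = seq(1L, by = 16L, length.out = nobs),
                        end = seq(16L, by = 16L, length.out = nobs))
  structure(list(values = values, doy = doy, flag = flag, periods = periods,
                 signals = signals, source = source, dims = dims),
            class = "coarse_series")
}

# Per-pixel retained (doy, value) pairs of one signal, sorted, NAs dropped;
# used to compare series regardless of internal slot layout.
series_pairs <- function(series, signal = 1L) {
  np <- dim(series$values)[1]
  lapply(seq_len(np), function(i) {
    v <- series$values[i, signal, ]
    d <- series$doy[i, ]
    keep <- !is.na(v) & !is.na(d)
    ord <- order(d[keep])
    cbind(doy = d[keep][ord], value = v[keep][ord])
  })
}

# A quick default landscape for tests.
tiny_truth <- function(n = 64L, coarse_factor = 8L, seed = 1L,
                       weights = NULL, patch_scale = 6) {
  if (is.null(weights)) weights <- c(0.10, 0.08, 0.07, 0.08, 0.30, 0.27, 0.10)
  generate_landscape(landscape_spec(n, n, coarse_factor = coarse_factor,
                                    class_weights = weights,
                                    patch_scale = patch_scale, seed = seed))
}

# A ground-truth landscape with a hand-authored class raster.
truth_from_raster <- function(class_raster, coarse_factor = 8L) {
  spec <- landscape_spec(nrow(class_raster), ncol(class_raster),
                         coarse_factor = coarse_factor, seed = 1L)
  structure(list(class_raster = class_raster,
                 phenology = default_phenology(), spec = spec),
            class = "ground_truth_landscape")
}

# Type-7 quantile computed from first principles (sort + linear
# interpolation between closest ranks), independent of stats::quantile.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}
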