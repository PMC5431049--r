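#' Build an acquisition calendar
#'
#' Regular revisit schedule with two alternating sensors; the second sensor
#' carries the scan-line-corrector failure flag (`slc_off`), which the fine
#' simulator renders as periodic diagonal data gaps. Each acquisition gets a
#' cloud/snow coverage fraction drawn uniformly from `cloud_range`.
#'
#' @param years Integer vector of acquisition years.
#' @param interval_days Days between successive acquisitions (default 16).
#' @param cloud_range Range of per-acquisition cloud/snow fractions.
#' @param slc_off Logical: does the second sensor operate SLC-off?
#' @param seed Seed for the cloud-fraction draws.
#' @return Data frame with columns date, year, doy, sensor, slc_off,
#'   cloud_fraction; dates strictly increasing.
#' @export
acquisition_calendar <- function(years = 2010L, interval_days = 16L,
                                 cloud_range = c(0.05, 0.5),
                                 slc_off = TRUE, seed = 1L) {
  rows <- do.call(rbind, lapply(sort(unique(as.integer(years))), function(y) {
    doy <- seq(8L, 360L, by = interval_days)
    data.frame(year = y, doy = doy)
  }))
  n <- nrow(rows)
  sensor <- rep(c("TM", "ETM+"), length.out = n)
  cal <- data.frame(
    date = as.Date(paste0(rows$year, "-01-01")) + rows$doy - 1L,
    year = rows$year, doy = rows$doy, sensor = sensor,
    slc_off = slc_off & sensor == "ETM+",
    cloud_fraction = with_seed(seed, runif(n, cloud_range[1], cloud_range[2])))
  stopifnot(all(diff(as.numeric(cal$date)) > 0))
  cal
}

# Spatially correlated mask covering approximately `fraction` of the grid:
# smoothed noise thresholded at its empirical (1 - fraction) quantile.
cloud_blob_mask <- function(n_rows, n_cols, fraction, blob_scale = 12) {
  if (fraction <= 0) return(matrix(FALSE, n_rows, n_cols))
  if (fraction >= 1) return(matrix(TRUE, n_rows, n_cols))
  f <- gauss_smooth(matrix(rnorm(n_rows * n_cols), n_rows, n_cols), blob_scale)
  f > quantile(f, 1 - fraction, type = 7)
}

# Diagonal SLC-off stripe gaps: TRUE where masked.
slc_stripe_mask <- function(n_rows, n_cols, period = 14L, width = 4L) {
  ((row(matrix(0, n_rows, n_cols)) + col(matrix(0, n_rows, n_cols))) %%
     period) < width
}

#' Simulate a fine-resolution observation stack
#'
#' For every acquisition in the calendar, per-pixel six-band reflectance is
#' the class phenology curve at the acquisition DOY plus Gaussian noise,
#' clipped to \[0, 1\]. The QA layer marks spatially correlated cloud/snow
#' blobs and, for SLC-off acquisitions, periodic diagonal stripes as
#' not-clear. Values at not-clear positions are overwritten with the
#' sentinel `-1`, so any downstream code that reads them is detectable.
#'
#' @param truth A `ground_truth_landscape`.
#' @param calendar An [acquisition_calendar()] data frame.
#' @param pixels Optional integer vector of fine-grid cell indices
#'   (column-major) at which to simulate; `NULL` simulates the full grid.
#' @param noise Logical; set `FALSE` for noiseless observations.
#' @param blob_scale Smoothing sigma (pixels) of the cloud blobs.
#' @param seed Seed for noise and cloud fields.
#' @return A `fine_series_stack`: list with `values` (array n_pixels x
#'   6 bands x n_acquisitions), `clear` (logical matrix n_pixels x
#'   n_acquisitions), `calendar`, `pixels`, `dims`, `bands`.
#' @export
simulate_fine_series <- function(truth, calendar, pixels = NULL,
                                 noise = TRUE, blob_scale = 12, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth_landscape"), nrow(calendar) > 0)
  spec <- truth$spec
  nr <- spec$n_rows; nc <- spec$n_cols
  all_pix <- is.null(pixels)
  if (all_pix) pixels <- seq_len(nr * nc)
  cls <- truth$class_raster[pixels]
  bands <- c("blue", "green", "red", "nir", "swir1", "swir2")
  nb <- length(bands); na <- nrow(calendar); np <- length(pixels)
  noise_sd <- vapply(bands, function(b) {
    truth$phenology$noise_sd[truth$phenology$domain == "fine" &
                               truth$phenology$signal == b][1]
  }, numeric(1))
  values <- array(NA_real_, dim = c(np, nb, na))
  clear <- matrix(TRUE, np, na)
  with_seed(seed, {
    for (a in seq_len(na)) {
      mask <- cloud_blob_mask(nr, nc, calendar$cloud_fraction[a], blob_scale)
      if (isTRUE(calendar$slc_off[a]))
        mask <- mask | slc_stripe_mask(nr, nc)
      clear[, a] <- !mask[pixels]
      for (b in seq_len(nb)) {
        curve <- phenology_curve(truth$phenology, "fine", bands[b],
                                 calendar$doy[a])
        v <- curve[1, cls]
        if (noise) v <- v + rnorm(np, sd = noise_sd[b])
        v <- pmin(pmax(v, 0), 1)
        v[!clear[, a]] <- -1  # sentinel: not-clear values must not be read
        values[, b, a] <- v
      }
    }
  })
  structure(list(values = values, clear = clear, calendar = calendar,
                 pixels = if (all_pix) NULL else pixels,
                 dims = c(nr, nc), bands = bands),
            class = "fine_series_stack")
}
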