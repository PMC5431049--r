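#' Single-date composite around a target day of year
#'
#' For each pixel and band, picks the value from the clear observation whose
#' day of year is closest to `target_doy` within the stated year (mid-summer
#' DOY 210 by default). Equidistant candidates are resolved in favour of the
#' earlier acquisition. Pixels with no clear observation are flagged missing.
#'
#' @param stack A `fine_series_stack`.
#' @param target_doy Target day of year.
#' @param year Year whose acquisitions are eligible.
#' @return A `composite_features` matrix (pixels x 6 band features) with
#'   attributes `type = "single_date"`, `pixels`, `dims`; missing pixels are
#'   all-`NA` rows.
#' @export
single_date_composite <- function(stack, target_doy = 210L, year = 2010L) {
  cal <- stack$calendar
  idx <- which(cal$year == year)
  if (length(idx) == 0L)
    stop("no acquisitions in year ", year)
  ord <- idx[order(abs(cal$doy[idx] - target_doy), cal$doy[idx])]
  np <- dim(stack$values)[1]
  out <- matrix(NA_real_, np, length(stack$bands))
  filled <- rep(FALSE, np)
  for (a in ord) {
    take <- !filled & stack$clear[, a]
    if (any(take)) {
      out[take, ] <- stack$values[take, , a]
      filled <- filled | take
    }
    if (all(filled)) break
  }
  colnames(out) <- paste0(stack$bands, "_doy", target_doy)
  structure(out, class = c("composite_features", "matrix", "array"),
            type = "single_date", pixels = stack$pixels, dims = stack$dims)
}

#' Spectral-temporal metrics over one or more years
#'
#' Per pixel and band, five statistics over all clear observations within
#' the given years: mean, median, standard deviation (sample, n-1),
#' 25th and 75th percentile (linear-interpolation quantiles). Pixels with
#' fewer than `min_obs` clear observations are flagged missing.
#'
#' @param stack A `fine_series_stack`.
#' @param years Years to pool; a single year gives the one-year metrics, a
#'   three-year epoch pools all its observations.
#' @param min_obs Minimum number of clear observations per pixel.
#' @return A `composite_features` matrix (pixels x 30 features: 6 bands x 5
#'   statistics, band-major order mean, median, sd, p25, p75).
#' @export
temporal_metrics <- function(stack, years, min_obs = 3L) {
  if (length(years) == 0L) stop("years must be non-empty")
  if (!all(years %in% stack$calendar$year))
    stop("years absent from the stack")
  idx <- which(stack$calendar$year %in% years)
  np <- dim(stack$values)[1]
  stats_names <- c("mean", "median", "sd", "p25", "p75")
  out <- matrix(NA_real_, np, length(stack$bands) * length(stats_names))
  colnames(out) <- as.vector(t(outer(stack$bands, stats_names, paste,
                                     sep = "_")))
  clear <- stack$clear[, idx, drop = FALSE]
  nclear <- rowSums(clear)
  ok <- nclear >= min_obs
  for (b in seq_along(stack$bands)) {
    v <- stack$values[, b, idx, drop = FALSE]
    dim(v) <- c(np, length(idx))
    v[!clear] <- NA_real_
    m <- rowMeans(v, na.rm = TRUE)
    # sample sd via sums of squares about the mean
    ss <- rowSums((v - m)^2, na.rm = TRUE)
    s <- ifelse(nclear > 1, sqrt(ss / (nclear - 1)), 0)
    q <- row_quantiles(v, c(0.25, 0.5, 0.75))
    cols <- (b - 1L) * 5L
    out[ok, cols + 1L] <- m[ok]
    out[ok, cols + 2L] <- q[ok, 2]
    out[ok, cols + 3L] <- s[ok]
    out[ok, cols + 4L] <- q[ok, 1]
    out[ok, cols + 5L] <- q[ok, 3]
  }
  structure(out, class = c("composite_features", "matrix", "array"),
            type = if (length(unique(years)) > 1L) "metrics_epoch"
                   else "metrics_1yr",
            pixels = stack$pixels, dims = stack$dims)
}

#' Missing-pixel flags of a composite feature table
#'
#' A pixel is missing when any of its features is undefined (no clear
#' observation close to the target date, or too few clear observations).
#'
#' @param features A `composite_features` matrix.
#' @return Logical vector, `TRUE` where the pixel is missing.
#' @export
missing_pixels <- function(features) {
  rowSums(is.na(unclass(features))) > 0L
}
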