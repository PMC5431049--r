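# Observations inside a coarse_series are "removed" by setting value and
# DOY to NA; the arrays stay rectangular so pixels remain aligned.

#' Merge Terra-like and Aqua-like series to an 8-day stream
#'
#' Per pixel, the union of both sensors' observations ordered by the
#' per-observation day of year; reliability flags and source tags are
#' carried through. Observations sharing a DOY are averaged into one
#' (the duplicate slot is emptied), keeping the better reliability flag.
#'
#' @param terra,aqua `coarse_series` objects on the same grid with the same
#'   signal set. `aqua` may be `NULL` or empty.
#' @return A merged `coarse_series` with source `"merged"`.
#' @export
merge_terra_aqua <- function(terra, aqua = NULL) {
  if (is.null(aqua) || dim(aqua$values)[3] == 0L) {
    out <- terra; out$source <- "merged"; return(out)
  }
  if (!identical(terra$dims, aqua$dims) ||
      !identical(terra$signals, aqua$signals))
    stop("terra and aqua series do not share grid and signal set")
  np <- dim(terra$values)[1]; ns <- dim(terra$values)[2]
  nobs <- dim(terra$values)[3] + dim(aqua$values)[3]
  doy <- cbind(terra$doy, aqua$doy)
  flag <- cbind(terra$flag, aqua$flag)
  src <- rep(c(terra$source, aqua$source),
             c(dim(terra$values)[3], dim(aqua$values)[3]))
  # per-pixel sort by DOY (NA last)
  ord <- t(apply(doy, 1L, order, na.last = TRUE))
  flat <- cbind(rep(seq_len(np), nobs), as.vector(ord))
  doy2 <- matrix(doy[flat], np, nobs)
  flag2 <- matrix(flag[flat], np, nobs)
  values <- array(NA_real_, c(np, ns, nobs))
  for (s in seq_len(ns)) {
    v <- cbind(matrix(terra$values[, s, ], np),
               matrix(aqua$values[, s, ], np))
    values[, s, ] <- matrix(v[flat], np, nobs)
  }
  # Merge duplicate DOYs into the earlier slot, empty the later one.
  # Only usable observations (flag 0/1) are averaged; a usable observation
  # paired with an unusable one wins outright, so screening before or after
  # merging yields the same retained series.
  qual <- function(f) ifelse(f == -1L, 4L, f)
  for (j in 2:nobs) {
    dup <- which(!is.na(doy2[, j]) & !is.na(doy2[, j - 1]) &
                   doy2[, j] == doy2[, j - 1])
    if (length(dup)) {
      ok1 <- flag2[dup, j - 1] %in% c(0L, 1L)
      ok2 <- flag2[dup, j] %in% c(0L, 1L)
      for (s in seq_len(ns)) {
        a <- values[dup, s, j - 1]; b <- values[dup, s, j]
        values[dup, s, j - 1] <- ifelse(ok1 & ok2, (a + b) / 2,
                                        ifelse(ok2 & !ok1, b, a))
      }
      take2 <- qual(flag2[dup, j]) < qual(flag2[dup, j - 1])
      flag2[dup, j - 1][take2] <- flag2[dup, j][take2]
      doy2[dup, j] <- NA_integer_
      for (s in seq_len(ns)) values[dup, s, j] <- NA_real_
    }
  }
  periods <- unique(rbind(terra$periods, aqua$periods))
  periods <- periods[order(periods$start), ]
  structure(list(values = values, doy = doy2, flag = flag2,
                 periods = periods, signals = terra$signals,
                 source = "merged", sources = src, dims = terra$dims),
            class = "coarse_series")
}

#' Screen observations by the reliability layer
#'
#' Removes observations flagged no-data (-1), snow/ice (2) or cloud (3);
#' good (0) and marginal (1) observations are retained.
#'
#' @param series A `coarse_series`.
#' @return The series with flagged observations removed.
#' @export
screen_reliability <- function(series) {
  bad <- !is.na(series$doy) & series$flag %in% c(-1L, 2L, 3L)
  if (any(bad)) {
    series$doy[bad] <- NA_integer_
    for (s in seq_along(series$signals)) {
      v <- matrix(series$values[, s, ], nrow = dim(series$values)[1])
      v[bad] <- NA_real_
      series$values[, s, ] <- v
    }
  }
  series
}

# Bin observations of one signal onto the regular grid: per-pixel bin means.
# Returns list(mean = np x ngrid matrix, nobs = count matrix).
.bin_to_grid <- function(values, doy, step, ngrid) {
  np <- nrow(values)
  bin <- pmin((doy - 1L) %/% step + 1L, ngrid)
  valid <- !is.na(values) & !is.na(bin)
  idx <- row(values)[valid] + (bin[valid] - 1L) * np
  cnt <- tabulate(idx, np * ngrid)
  sums <- numeric(np * ngrid)
  g <- rowsum(values[valid], idx)
  sums[as.integer(rownames(g))] <- g
  list(mean = matrix(ifelse(cnt > 0, sums / cnt, NA_real_), np, ngrid),
       count = matrix(cnt, np, ngrid))
}

# Linear gap interpolation along rows; leading/trailing gaps take the
# nearest observed value. Rows with < min_pts observations become all-NA.
.interp_rows <- function(m, min_pts = 2L) {
  t(apply(m, 1L, function(x) {
    ok <- !is.na(x)
    if (sum(ok) < min_pts) return(rep(NA_real_, length(x)))
    approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
  }))
}

# Remainder of one gap-free regular series against its seasonal structure.
# With >= 2 full cycles: robust STL remainder. With a single cycle an STL
# seasonal would absorb any spike (every cycle copy agrees), so the
# remainder is taken against a leave-one-out running median over the
# circular neighbourhood instead.
.seasonal_remainder <- function(x, period, half_w = 2L) {
  n <- length(x)
  if (n >= 2L * period) {
    fit <- stl(ts(x, frequency = period), s.window = "periodic",
               robust = TRUE)
    as.numeric(fit$time.series[, "remainder"])
  } else {
    idx <- outer(seq_len(n), c(-(half_w:1), 1:half_w),
                 function(t, d) (t + d - 1L) %% n + 1L)
    med <- apply(matrix(x[idx], n), 1L, median)
    x - med
  }
}

# Iterative despiking of one pixel-signal series: drop the observations in
# the worst offending grid bin, refit, repeat. Removing one spike at a time
# keeps its neighbours (whose running-median remainder the spike perturbs)
# from being dragged over the threshold, and makes the screen idempotent.
.despike_obs <- function(values, bins, ngrid, k_sd, max_iter = 5L) {
  removed <- integer(0)
  keep <- which(!is.na(values) & !is.na(bins))
  for (it in seq_len(max_iter)) {
    cnt <- tabulate(bins[keep], ngrid)
    sums <- rep(0, ngrid)
    for (o in keep) sums[bins[o]] <- sums[bins[o]] + values[o]
    ok <- cnt > 0
    if (sum(ok) < 2L) break
    x <- approx(which(ok), sums[ok] / cnt[ok], xout = seq_len(ngrid),
                rule = 2)$y
    rem <- .seasonal_remainder(x, ngrid)
    rsd <- mad(rem)
    if (rsd <= 0) break
    bad <- which(abs(rem) > k_sd * rsd & ok)
    if (length(bad) == 0L) break
    worst <- bad[which.max(abs(rem)[bad])]
    drop <- keep[bins[keep] == worst]
    removed <- c(removed, drop)
    keep <- setdiff(keep, drop)
  }
  removed
}

#' Remove residual time-series outliers by seasonal decomposition
#'
#' Places each pixel's series per signal on a regular `step_days` grid
#' (gaps linearly interpolated for the decomposition only) and removes
#' observations whose remainder — the series minus its seasonal structure —
#' exceeds `k_sd` times the robust standard deviation (MAD) of the
#' remainder. Series spanning at least two full cycles are decomposed with
#' seasonal-trend decomposition based on loess (robust fitting, periodic
#' seasonal). A single-cycle series cannot be decomposed that way (a
#' periodic seasonal fitted to one cycle reproduces every point, outliers
#' included), so its remainder is taken against a leave-one-out circular
#' running median, which is robust to isolated spikes. Outliers are removed
#' one grid bin at a time, worst first, refitting in between, so that a
#' spike cannot drag its neighbours over the threshold; the iteration makes
#' the screen idempotent.
#'
#' @param series A `coarse_series` (merged and reliability-screened).
#' @param step_days Regular grid step in days (default 8).
#' @param k_sd Removal threshold in robust standard deviations.
#' @param min_obs Below this many observations a pixel's signal is left
#'   unscreened (with a warning summary).
#' @return The series with outlying observations removed.
#' @export
stl_outlier_removal <- function(series, step_days = 8L, k_sd = 3,
                                min_obs = 10L) {
  np <- dim(series$values)[1]; ns <- length(series$signals)
  ngrid <- as.integer(ceiling(365 / step_days))
  skipped <- 0L
  bin <- pmin((series$doy - 1L) %/% step_days + 1L, ngrid)
  for (s in seq_len(ns)) {
    v <- matrix(series$values[, s, ], np)
    for (i in seq_len(np)) {
      nobs_i <- sum(!is.na(v[i, ]))
      if (nobs_i == 0L) next
      if (nobs_i < min_obs) {
        skipped <- skipped + 1L
        next
      }
      drop <- .despike_obs(v[i, ], bin[i, ], ngrid, k_sd)
      if (length(drop)) v[i, drop] <- NA_real_
    }
    series$values[, s, ] <- v
  }
  if (skipped > 0L)
    warning(skipped, " pixel-signal series too short for STL screening; ",
            "left unscreened")
  # a DOY with all signals removed is an empty slot
  any_left <- Reduce(`|`, lapply(seq_len(ns), function(s)
    !is.na(matrix(series$values[, s, ], np))))
  series$doy[!any_left] <- NA_integer_
  series
}

# Savitzky-Golay smoothing matrix on a regular grid of n points:
# local least-squares polynomial of order `poly_order` over a window of
# half-width `half_window`, shrunk asymmetrically at the edges.
sg_matrix <- function(n, half_window, poly_order) {
  if (poly_order >= 2 * half_window + 1)
    stop("poly_order must be < window length")
  W <- matrix(0, n, n)
  for (t in seq_len(n)) {
    w <- max(1L, t - half_window):min(n, t + half_window)
    X <- outer(w - t, 0:poly_order, `^`)
    W[t, w] <- solve(crossprod(X), t(X))[1L, ]
  }
  W
}

#' Savitzky-Golay smoothing onto the regular grid
#'
#' Each pixel's screened series is placed on the regular `step_days` grid
#' (per-bin means, gaps linearly interpolated, edge gaps taking the nearest
#' value) and smoothed by a local least-squares polynomial of order
#' `poly_order` over a window of `2 * half_window + 1` grid points; edge
#' windows shrink asymmetrically. The filter reproduces polynomials up to
#' `poly_order` exactly.
#'
#' @param series A `coarse_series`.
#' @param half_window Window half-width in grid steps.
#' @param poly_order Polynomial order (< window length).
#' @param step_days Grid step in days.
#' @param min_obs Pixels with fewer observations per signal are marked
#'   missing (all-NA).
#' @return A `coarse_series_smooth`: list with `values` (array pixels x
#'   signals x grid points), `grid_doy`, `signals`, `dims`.
#' @export
savitzky_golay_smooth <- function(series, half_window = 4L, poly_order = 2L,
                                  step_days = 8L, min_obs = NULL) {
  if (is.null(min_obs)) min_obs <- poly_order + 1L
  np <- dim(series$values)[1]; ns <- length(series$signals)
  ngrid <- as.integer(ceiling(365 / step_days))
  W <- sg_matrix(ngrid, half_window, poly_order)
  out <- array(NA_real_, c(np, ns, ngrid))
  for (s in seq_len(ns)) {
    v <- matrix(series$values[, s, ], np)
    binned <- .bin_to_grid(v, series$doy, step_days, ngrid)
    filled <- .interp_rows(binned$mean, min_pts = 2L)
    enough <- rowSums(!is.na(v)) >= min_obs & !is.na(filled[, 1])
    sm <- filled %*% t(W)
    sm[!enough, ] <- NA_real_
    out[, s, ] <- sm
  }
  structure(list(values = out,
                 grid_doy = (seq_len(ngrid) - 1) * step_days + (step_days + 1) / 2,
                 signals = series$signals, dims = series$dims),
            class = "coarse_series_smooth")
}

#' Seasonal statistics from a smoothed series
#'
#' For each signal and season — spring (March-May, DOY 60-151), summer
#' (June-August, DOY 152-243), autumn (September-November, DOY 244-334) on
#' a non-leap calendar — computes mean, minimum, maximum, range and
#' standard deviation over the grid points falling in the season: 6 signals
#' x 5 statistics x 3 seasons = 90 features per pixel.
#'
#' @param smoothed A `coarse_series_smooth`.
#' @return A `seasonal_features` matrix (pixels x 90) with feature names
#'   `<signal>_<season>_<stat>`; missing pixels are all-`NA` rows.
#' @export
seasonal_statistics <- function(smoothed) {
  seasons <- list(spring = c(60, 151), summer = c(152, 243),
                  autumn = c(244, 334))
  stats_names <- c("mean", "min", "max", "range", "sd")
  np <- dim(smoothed$values)[1]
  cols <- as.vector(vapply(smoothed$signals, function(sg)
    as.vector(vapply(names(seasons), function(se)
      paste(sg, se, stats_names, sep = "_"), character(5))),
    character(15)))
  out <- matrix(NA_real_, np, length(cols), dimnames = list(NULL, cols))
  k <- 0L
  for (s in seq_along(smoothed$signals)) {
    v <- matrix(smoothed$values[, s, ], np)
    for (se in seq_along(seasons)) {
      in_se <- smoothed$grid_doy >= seasons[[se]][1] &
        smoothed$grid_doy <= seasons[[se]][2]
      if (!any(in_se)) stop("season without grid points: ",
                            names(seasons)[se])
      vv <- v[, in_se, drop = FALSE]
      mn <- rowMeans(vv)
      lo <- apply(vv, 1L, min); hi <- apply(vv, 1L, max)
      sdv <- apply(vv, 1L, sd)
      out[, k + 1L] <- mn; out[, k + 2L] <- lo; out[, k + 3L] <- hi
      out[, k + 4L] <- hi - lo; out[, k + 5L] <- sdv
      k <- k + 5L
    }
  }
  structure(out, class = c("seasonal_features", "matrix", "array"),
            dims = smoothed$dims)
}
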