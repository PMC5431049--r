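#' Simulate Terra-like and Aqua-like coarse composite series
#'
#' Emulates two 16-day vegetation-index composite streams whose start days
#' are offset by 8 days. Per coarse pixel and composite period the signal is
#' the area-weighted mean, over the constituent fine pixels, of the class
#' phenology curves evaluated at a per-pixel random day within the period,
#' plus Gaussian noise. A reliability flag (-1 no-data, 0 good, 1 marginal,
#' 2 snow/ice, 3 cloud) is drawn per observation; observations flagged
#' no-data/snow/cloud carry the sentinel value -1.
#'
#' @param truth A `ground_truth_landscape`.
#' @param year Composite year (used for the period table only).
#' @param step_days Composite length in days; must be 16.
#' @param flag_probs Named probabilities for marginal, snow, cloud, nodata
#'   flags (remainder is good).
#' @param noise Logical; `FALSE` for noiseless signals.
#' @param seed Seed for DOY sampling, noise and flags.
#' @return List with elements `terra` and `aqua`, each a `coarse_series`.
#' @export
simulate_coarse_series <- function(truth, year = 2010L, step_days = 16L,
                                   flag_probs = c(marginal = 0.05,
                                                  snow = 0.03, cloud = 0.06,
                                                  nodata = 0.01),
                                   noise = TRUE, seed = 1L) {
  if (step_days <= 0) stop("step_days must be positive")
  stopifnot(step_days == 16L)
  frac <- block_class_fractions(truth$class_raster,
                                truth$spec$coarse_factor)
  dims <- dim(frac)[1:2]
  fr <- matrix(frac, nrow = prod(dims))  # pixels x classes (legend order)
  with_seed(seed, {
    terra <- .one_coarse_series(truth, fr, dims, year, step_days,
                                start_doy = 1L, flag_probs, noise, "terra")
    aqua <- .one_coarse_series(truth, fr, dims, year, step_days,
                               start_doy = 9L, flag_probs, noise, "aqua")
  })
  list(terra = terra, aqua = aqua)
}

.one_coarse_series <- function(truth, fr, dims, year, step_days, start_doy,
                               flag_probs, noise, source) {
  signals <- c("ndvi", "evi", "blue", "red", "nir", "swir")
  starts <- seq(start_doy, 365L, by = step_days)
  np <- nrow(fr); nobs <- length(starts); ns <- length(signals)
  noise_sd <- vapply(signals, function(s) {
    truth$phenology$noise_sd[truth$phenology$domain == "coarse" &
                               truth$phenology$signal == s][1]
  }, numeric(1))
  values <- array(NA_real_, dim = c(np, ns, nobs))
  doy <- matrix(NA_integer_, np, nobs)
  flag <- matrix(0L, np, nobs)
  pr <- c(good = 1 - sum(flag_probs), flag_probs[c("marginal", "snow",
                                                   "cloud", "nodata")])
  codes <- c(0L, 1L, 2L, 3L, -1L)
  for (o in seq_len(nobs)) {
    width <- min(step_days, 365L - starts[o] + 1L)
    doy[, o] <- starts[o] + sample.int(width, np, replace = TRUE) - 1L
    flag[, o] <- codes[sample.int(5L, np, replace = TRUE, prob = pr)]
    for (s in seq_len(ns)) {
      curves <- phenology_curve(truth$phenology, "coarse", signals[s],
                                unique(doy[, o]))
      cm <- curves[match(doy[, o], unique(doy[, o])), , drop = FALSE]
      v <- rowSums(fr * cm)
      if (noise) v <- v + rnorm(np, sd = noise_sd[s])
      lo <- if (signals[s] %in% c("ndvi", "evi")) -1 else 0
      v <- pmin(pmax(v, lo), 1)
      v[flag[, o] %in% c(-1L, 2L, 3L)] <- -1  # sentinel at unusable obs
      values[, s, o] <- v
    }
  }
  periods <- data.frame(year = year, start = starts,
                        end = pmin(starts + step_days - 1L, 365L))
  structure(list(values = values, doy = doy, flag = flag, periods = periods,
                 signals = signals, source = source, dims = dims),
            class = "coarse_series")
}
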