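test_that("terra/aqua merge orders, deduplicates and commutes with screening", {
  terra <- make_coarse(array(0.2, c(2, 1, 1)), matrix(12L, 2, 1))
  aqua <- make_coarse(array(0.6, c(2, 1, 1)), matrix(20L, 2, 1),
                      source = "aqua")
  m <- merge_terra_aqua(terra, aqua)
  expect_equal(series_pairs(m)[[1]],
               cbind(doy = c(12, 20), value = c(0.2, 0.6)))

  # duplicate DOY from both sensors -> averaged into one observation
  aqua2 <- make_coarse(array(0.6, c(2, 1, 1)), matrix(12L, 2, 1),
                       source = "aqua")
  m2 <- merge_terra_aqua(terra, aqua2)
  expect_equal(series_pairs(m2)[[1]], cbind(doy = 12, value = 0.4))

  # empty aqua -> terra unchanged
  m3 <- merge_terra_aqua(terra, NULL)
  expect_equal(series_pairs(m3), series_pairs(terra))
  expect_error(merge_terra_aqua(terra, make_coarse(array(0.1, c(3, 1, 1)),
                                                   matrix(5L, 3, 1),
                                                   dims = c(3L, 1L))),
               "share grid")

  # merge-then-screen equals screen-then-merge on random flagged series
  set.seed(41)
  np <- 30
  mk <- function(src, start) {
    nobs <- 12
    doy <- matrix(rep(seq(start, by = 16, length.out = nobs), each = np) +
                    sample(0:15, np * nobs, TRUE), np, nobs)
    make_coarse(array(runif(np * 2 * nobs), c(np, 2, nobs)),
                doy, flag = matrix(sample(c(-1L, 0L, 1L, 2L, 3L),
                                          np * nobs, TRUE), np, nobs),
                signals = c("a", "b"), source = src, dims = c(np, 1L))
  }
  t1 <- mk("terra", 1); a1 <- mk("aqua", 9)
  ab <- screen_reliability(merge_terra_aqua(t1, a1))
  ba <- merge_terra_aqua(screen_reliability(t1), screen_reliability(a1))
  for (s in 1:2)
    expect_equal(series_pairs(ab, s), series_pairs(ba, s))
})

test_that("reliability screening removes exactly the flagged observations", {
  np <- 4; nobs <- 46
  flag <- matrix(0L, np, nobs)
  flag[1, 1:5] <- 3L
  s <- make_coarse(array(runif(np * 1 * nobs), c(np, 1, nobs)),
                   matrix(rep(seq(4, by = 8, length.out = nobs), each = np),
                          np, nobs),
                   flag = flag)
  out <- screen_reliability(s)
  expect_identical(sum(!is.na(out$values[1, 1, ])), 41L)
  expect_identical(sum(!is.na(out$values[2, 1, ])), 46L)

  all_bad <- s
  all_bad$flag[] <- 2L
  out2 <- screen_reliability(all_bad)
  expect_true(all(is.na(out2$values)))
})

# one pixel, one observation per 8-day bin at the bin centre
regular_series <- function(values, nsig = 1) {
  nobs <- length(values)
  doy <- matrix(round((seq_len(nobs) - 1) * 8 + 4.5), 1, nobs)
  make_coarse(array(rep(values, nsig), c(1, nsig, nobs)), doy)
}

test_that("STL screening removes spikes and nothing else", {
  const <- regular_series(rep(0.5, 46))
  out <- stl_outlier_removal(const)
  expect_false(anyNA(out$values))

  doy <- round((0:45) * 8 + 4.5)
  wave <- 0.5 + 0.3 * sin(2 * pi * doy / 365)
  spike_at <- 20L
  x <- wave; x[spike_at] <- x[spike_at] + 0.5
  s <- regular_series(x)
  out2 <- stl_outlier_removal(s, k_sd = 3)
  removed <- which(is.na(out2$values[1, 1, ]))
  expect_identical(removed, spike_at)

  # idempotence: rerunning on the screened series removes nothing further
  out3 <- stl_outlier_removal(out2, k_sd = 3)
  expect_identical(which(is.na(out3$values[1, 1, ])), removed)

  # too-short series: left unscreened with a warning
  short <- regular_series(rnorm(5))
  expect_warning(out4 <- stl_outlier_removal(short), "too short")
  expect_false(anyNA(out4$values))
})

test_that("Savitzky-Golay reproduces polynomials and the window oracle", {
  t <- 1:46
  quad <- 0.2 + 0.01 * t - 0.0002 * t^2
  sm <- savitzky_golay_smooth(regular_series(quad), half_window = 4,
                              poly_order = 2)
  expect_equal(sm$values[1, 1, ], quad, tolerance = 1e-9)

  lin <- 0.1 + 0.005 * t
  sm1 <- savitzky_golay_smooth(regular_series(lin), half_window = 5,
                               poly_order = 1)
  expect_equal(sm1$values[1, 1, ], lin, tolerance = 1e-9)

  # interior windows match a per-window least-squares fit oracle
  set.seed(51)
  y <- runif(46)
  h <- 4; ord <- 2
  sm2 <- savitzky_golay_smooth(regular_series(y), half_window = h,
                               poly_order = ord)
  for (tt in (h + 1):(46 - h)) {
    w <- (tt - h):(tt + h)
    fit <- lm(y[w] ~ poly(w - tt, ord, raw = TRUE))
    expect_equal(sm2$values[1, 1, tt], unname(coef(fit)[1]),
                 tolerance = 1e-9)
  }
  expect_error(savitzky_golay_smooth(regular_series(y), half_window = 1,
                                     poly_order = 3), "window")

  # linearity on a shared grid and gap pattern
  y2 <- runif(46)
  lhs <- savitzky_golay_smooth(regular_series(2 * y + 3 * y2))$values
  rhs <- 2 * savitzky_golay_smooth(regular_series(y))$values +
    3 * savitzky_golay_smooth(regular_series(y2))$values
  expect_equal(lhs, rhs, tolerance = 1e-10)

  # insufficient observations -> missing pixel
  sparse <- make_coarse(array(0.5, c(1, 1, 2)), matrix(c(10L, 50L), 1, 2))
  expect_true(all(is.na(savitzky_golay_smooth(sparse,
                                              min_obs = 3)$values)))
})

test_that("seasonal statistics cover 6 signals x 5 stats x 3 seasons", {
  const <- regular_series(rep(0.5, 46), nsig = 6)
  const$signals <- c("ndvi", "evi", "blue", "red", "nir", "swir")
  sm <- savitzky_golay_smooth(const)
  sf <- seasonal_statistics(sm)
  expect_identical(ncol(sf), 90L)
  expect_equal(unname(unclass(sf)[1, "ndvi_summer_mean"]), 0.5)
  expect_equal(unname(unclass(sf)[1, "swir_autumn_range"]), 0)
  expect_equal(unname(unclass(sf)[1, "evi_spring_sd"]), 0)

  # linear ramp over the year: summer mean > spring mean > 0
  grid_doy <- (0:45) * 8 + 4.5
  ramp <- structure(list(values = array(rep(grid_doy / 365, each = 1),
                                        c(1, 1, 46)),
                         grid_doy = grid_doy, signals = "ndvi",
                         dims = c(1L, 1L)),
                    class = "coarse_series_smooth")
  sfr <- unclass(seasonal_statistics(ramp))
  expect_gt(sfr[1, "ndvi_summer_mean"], sfr[1, "ndvi_spring_mean"])
  expect_gt(sfr[1, "ndvi_spring_mean"], 0)

  # values outside March-November never reach the features
  ramp2 <- ramp
  ramp2$values[1, 1, ramp$grid_doy < 60 | ramp$grid_doy > 334] <- 99
  expect_identical(unclass(seasonal_statistics(ramp2)), unclass(sfr))
})

test_that("the coarse preparation pipeline is deterministic", {
  truth <- tiny_truth(n = 32, seed = 61)
  co <- simulate_coarse_series(truth, seed = 62)
  f1 <- suppressWarnings(prepare_seasonal_features(co$terra, co$aqua))
  f2 <- suppressWarnings(prepare_seasonal_features(co$terra, co$aqua))
  expect_identical(f1, f2)
})
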