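test_that("minimum-distance sampling honours the constraint", {
  s0 <- sample_training_pixels(c(10, 10), pixel_size = 240, n_target = 100,
                               min_dist = 0, seed = 1)
  expect_identical(nrow(s0), 100L)

  s1 <- suppressMessages(
    sample_training_pixels(c(10, 10), pixel_size = 240, n_target = 100,
                           min_dist = 1000, seed = 2))
  # brute-force pairwise check in metres
  d <- as.matrix(dist(cbind(s1$row, s1$col) * 240))
  diag(d) <- Inf
  expect_true(all(d >= 1000))
  expect_lt(nrow(s1), 100L)

  expect_identical(
    suppressMessages(sample_training_pixels(c(20, 20), 240, 50, 1000, seed = 7)),
    suppressMessages(sample_training_pixels(c(20, 20), 240, 50, 1000, seed = 7)))
})

test_that("reference fractions count fine pixels correctly", {
  lc <- matrix(6L, 8, 8)
  lc[1:4, ] <- 2L  # 32 evergreen, 32 barren
  fr <- compute_reference_fractions(lc, 8L)
  expect_equal(c(fr$deciduous[1, 1], fr$evergreen[1, 1], fr$mixed[1, 1]),
               c(0, 0.5, 0))
  expect_equal(fr$overall[1, 1], 0.5)

  # all-missing block dropped
  fr2 <- compute_reference_fractions(matrix(NA_integer_, 8, 8), 8L)
  expect_true(is.na(fr2$overall[1, 1]))

  # missing pixels leave the denominator; > 50% missing drops the block
  lc3 <- matrix(1L, 8, 8)
  lc3[, 1:2] <- NA
  fr3 <- compute_reference_fractions(lc3, 8L)
  expect_equal(fr3$deciduous[1, 1], 1)
  lc3[, 1:5] <- NA
  expect_true(is.na(compute_reference_fractions(lc3, 8L)$deciduous[1, 1]))

  # brute-force tally oracle on a random map with scattered missing
  set.seed(71)
  lc4 <- matrix(sample(c(1:7, NA), 32 * 32, TRUE), 32, 32)
  fr4 <- compute_reference_fractions(lc4, 8L)
  for (i in 1:4) for (j in 1:4) {
    block <- lc4[(i - 1) * 8 + 1:8, (j - 1) * 8 + 1:8]
    nv <- sum(!is.na(block))
    if (mean(is.na(block)) > 0.5) {
      expect_true(is.na(fr4$deciduous[i, j]))
    } else {
      expect_equal(fr4$deciduous[i, j], sum(block == 1, na.rm = TRUE) / nv)
      expect_equal(fr4$overall[i, j],
                   sum(block %in% 1:3, na.rm = TRUE) / nv)
    }
  }
  expect_error(compute_reference_fractions(matrix(1L, 9, 9), 8L), "nest")
})

test_that("fraction forests fit, stay independent, and recover signals", {
  set.seed(72)
  x <- matrix(runif(200 * 5), 200, 5, dimnames = list(NULL, paste0("f", 1:5)))
  fr <- data.frame(deciduous = rep(0.4, 200), evergreen = runif(200),
                   mixed = runif(200))
  m <- train_fraction_models(x, fr, rf_params(n_trees = 50, seed = 3))
  p <- predict_fractions(m, x)
  expect_true(all(p$deciduous == 0.4))

  # response equal to one feature: near-perfect in-sample correlation
  set.seed(73)
  x2 <- matrix(runif(2000 * 10), 2000, 10,
               dimnames = list(NULL, paste0("f", 1:10)))
  fr2 <- data.frame(deciduous = x2[, 1], evergreen = runif(2000),
                    mixed = runif(2000))
  m2 <- train_fraction_models(x2, fr2, rf_params(n_trees = 200, seed = 4))
  p2 <- predict_fractions(m2, x2)
  expect_gte(cor(p2$deciduous, x2[, 1]), 0.99)

  # altering the mixed-forest responses never changes the deciduous model
  fr3 <- fr2; fr3$mixed <- runif(2000)
  m3 <- train_fraction_models(x2, fr3, rf_params(n_trees = 200, seed = 4))
  expect_identical(predict_fractions(m3, x2)$deciduous, p2$deciduous)

  expect_error(train_fraction_models(x2[0, ], fr2[0, ]), "empty")
})

constant_models <- function(d, e, m) {
  structure(list(models = list(deciduous = list(constant = d),
                               evergreen = list(constant = e),
                               mixed = list(constant = m)),
                 features = c("f1", "f2"), params = rf_params()),
            class = "fraction_models")
}

test_that("fraction prediction sums, clips, and is idempotent under clipping", {
  x <- matrix(0, 3, 2, dimnames = list(NULL, c("f1", "f2")))
  p <- predict_fractions(constant_models(0.2, 0.3, 0.1), x)
  expect_equal(p$overall, rep(0.6, 3))
  p2 <- predict_fractions(constant_models(0.5, 0.5, 0.4), x)
  expect_equal(p2$overall, rep(1, 3))
  # re-clipping changes nothing
  for (k in names(p2)) expect_equal(pmin(pmax(p2[[k]], 0), 1), p2[[k]])
  # missing features propagate
  x[2, 1] <- NA
  p3 <- predict_fractions(constant_models(0.2, 0.3, 0.1), x)
  expect_true(is.na(p3$overall[2]))
  colnames(x) <- c("g1", "g2")
  expect_error(predict_fractions(constant_models(0.1, 0.1, 0.1), x),
               "schema")
})

test_that("NRMSE matches Eq.-style hand computation and its oracle", {
  expect_equal(nrmse(c(0.2, 0.4), c(0.4, 0.2)), 2 / 3, tolerance = 1e-12)
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_true(is.na(nrmse(c(0.1, 0.2), c(0, 0))))
  # scale invariance
  p <- runif(50); r <- runif(50)
  expect_equal(nrmse(3.7 * p, 3.7 * r), nrmse(p, r), tolerance = 1e-12)
  # brute-force oracle on 100 random vectors
  set.seed(74)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    p <- runif(n); r <- runif(n, 0.01, 1)
    acc <- 0
    for (k in seq_len(n)) acc <- acc + (p[k] - r[k])^2
    expect_equal(nrmse(p, r), sqrt(acc / n) / (sum(r) / n),
                 tolerance = 1e-12)
  }
})

test_that("fraction validation stratifies on the predicted map", {
  set.seed(75)
  pred <- list(deciduous = matrix(runif(400, 0, 0.5), 20, 20),
               evergreen = matrix(0, 20, 20),
               mixed = matrix(0, 20, 20))
  pred$deciduous[1:10, ] <- 0
  pred$overall <- pred$deciduous
  class(pred) <- "fraction_map"
  ref <- pred
  rep1 <- validate_fractions(pred, ref, n_per_stratum = 50, seed = 3)
  expect_equal(rep1$nrmse[rep1$target == "overall"], 0)
  expect_equal(rep1$pearson_r[rep1$target == "overall"], 1)
  cells <- attr(rep1, "cells")
  # exactly min(n_per_stratum, stratum size) per disjoint stratum
  expect_identical(length(cells), 100L)
  expect_identical(anyDuplicated(cells), 0L)
  expect_identical(sum(pred$overall[cells] > 0), 50L)
  expect_identical(sum(pred$overall[cells] == 0), 50L)
  # exhaustion when a stratum is small
  pred_small <- pred
  pred_small$overall[] <- 0.3
  rep2 <- validate_fractions(pred_small, ref, n_per_stratum = 1000, seed = 1)
  expect_identical(rep2$n[1], 400L)
  # determinism
  expect_identical(validate_fractions(pred, ref, 50, seed = 8),
                   validate_fractions(pred, ref, 50, seed = 8))
})
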