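#' Update a year-2000 tree-cover layer with loss and gain masks
#'
#' Pixels flagged as forest loss are assigned 0 percent tree cover; pixels
#' flagged as gain are assigned 100 percent. When both flags are set, loss
#' wins (applied last). The share of relabelled pixels among pixels with
#' more than 25 percent initial tree cover is recorded as a bookkeeping
#' attribute.
#'
#' @param tc2000 Numeric matrix of tree-cover percent in \[0, 100\]
#'   (`NA` = nodata).
#' @param loss_mask,gain_mask Logical matrices aligned with `tc2000`.
#' @return Updated tree-cover matrix with attribute `relabelled_gt25`.
#' @export
update_tree_cover <- function(tc2000, loss_mask, gain_mask) {
  if (!identical(dim(tc2000), dim(loss_mask)) ||
      !identical(dim(tc2000), dim(gain_mask)))
    stop("grids are not aligned")
  out <- tc2000
  out[gain_mask] <- 100
  out[loss_mask] <- 0
  out[is.na(tc2000)] <- NA
  gt25 <- !is.na(tc2000) & tc2000 > 25
  changed <- (loss_mask | gain_mask) & !is.na(tc2000)
  attr(out, "relabelled_gt25") <-
    if (any(gt25)) sum(changed & gt25) / sum(gt25) else NA_real_
  out
}

#' Threshold tree cover into a forest/non-forest map
#'
#' Forest where tree cover is strictly greater than the threshold
#' (default 30 percent, the dryland forest definition); nodata propagates.
#'
#' @param cover Numeric matrix of tree-cover percent.
#' @param threshold_pct Threshold in \[0, 100\].
#' @return Logical matrix (`TRUE` = forest, `NA` = nodata).
#' @export
threshold_forest <- function(cover, threshold_pct = 30) {
  stopifnot(threshold_pct >= 0, threshold_pct <= 100)
  cover > threshold_pct
}

#' Block-mean aggregation to a coarser grid
#'
#' Averages values over non-overlapping `factor` x `factor` windows,
#' ignoring nodata cells (an all-nodata block is nodata). Trailing rows or
#' columns that do not fill a block are dropped.
#'
#' @param raster Numeric matrix (`NA` = nodata).
#' @param factor Integer aggregation factor (>= 2, 1 returns the input).
#' @return Matrix of block means.
#' @export
aggregate_mean <- function(raster, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(raster)
  stopifnot(factor >= 2L)
  nr <- nrow(raster) %/% factor; nc <- ncol(raster) %/% factor
  if (nr < 1L || nc < 1L) stop("aggregation factor exceeds raster size")
  r <- raster[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  br <- (row(r) - 1L) %/% factor
  bc <- (col(r) - 1L) %/% factor
  id <- br + nr * bc + 1L
  valid <- !is.na(r)
  sums <- numeric(nr * nc); cnt <- tabulate(id[valid], nr * nc)
  g <- rowsum(r[valid], id[valid])
  sums[as.integer(rownames(g))] <- g
  matrix(ifelse(cnt > 0, sums / cnt, NA_real_), nr, nc)
}

#' Multi-scale agreement between two continuous cover maps
#'
#' At each aggregation factor, compares the maps over pixels where either
#' map reports cover greater than zero (union mask): Pearson r and the
#' ordinary-least-squares slope of `mapB` regressed on `mapA` by default
#' (`direction = "B_on_A"`; set `"A_on_B"` for the reverse).
#'
#' @param mapA,mapB Aligned numeric matrices at native scale.
#' @param factors Integer aggregation factors; 1 = native.
#' @param direction Regression direction.
#' @return An `agreement_report` data frame: factor, r, slope, n.
#' @export
agreement <- function(mapA, mapB, factors = c(1L, 4L, 20L),
                      direction = c("B_on_A", "A_on_B")) {
  direction <- match.arg(direction)
  if (!identical(dim(mapA), dim(mapB))) stop("grids are not aligned")
  rows <- lapply(factors, function(f) {
    a <- as.vector(aggregate_mean(mapA, f))
    b <- as.vector(aggregate_mean(mapB, f))
    keep <- !is.na(a) & !is.na(b) & (a > 0 | b > 0)
    if (sum(keep) <= 2L) stop("fewer than 3 pixels to compare at factor ", f)
    a <- a[keep]; b <- b[keep]
    x <- if (direction == "B_on_A") a else b
    y <- if (direction == "B_on_A") b else a
    data.frame(factor = f, r = cor(a, b),
               slope = sum((x - mean(x)) * (y - mean(y))) /
                 sum((x - mean(x))^2),
               n = length(a))
  })
  structure(do.call(rbind, rows),
            class = c("agreement_report", "data.frame"),
            direction = direction)
}

#' Per-zone forest cover percentages
#'
#' For each zone label, 100 times the mean forest value over the zone:
#' binary maps give percent forest area, fractional maps give mean percent
#' cover.
#'
#' @param forest Numeric or logical matrix (binary forest or fraction in
#'   \[0, 1\]); `NA` excluded.
#' @param zones Integer matrix of zone labels aligned with `forest`.
#' @return Data frame with `zone`, `percent_forest`, `n_pixels`.
#' @export
zonal_forest_percent <- function(forest, zones) {
  if (!identical(dim(forest), dim(zones))) stop("grids are not aligned")
  f <- as.numeric(forest); z <- as.vector(zones)
  keep <- !is.na(f) & !is.na(z)
  if (!any(keep)) stop("no valid pixels")
  agg <- tapply(f[keep], z[keep], mean)
  data.frame(zone = as.integer(names(agg)),
             percent_forest = 100 * as.numeric(agg),
             n_pixels = as.integer(table(z[keep])[names(agg)]))
}
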