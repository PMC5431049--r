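---
title: "Multi-resolution forest-cover mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution forest-cover mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drycover)
```

## The problem

Dryland forests are sparse, patchy, and phenologically diverse, which makes
them hard to map from any single satellite image: a mid-summer scene cannot
separate a senesced grassland from bare ground, nor a deciduous stand from a
wetland shrub layer, because their reflectance overlaps on that one date.
`drycover` implements a two-resolution strategy for this setting:

1. **Fine resolution (30 m)** — classify land cover into a seven-class
   legend (deciduous, evergreen and mixed forest; non-woody wetland;
   herbaceous land; barren land; water) from *spectral-temporal metrics*:
   per-pixel summary statistics of each reflectance band over all clear
   observations in one or several years. Forest is defined as tree cover
   above 30%; mixed forest is forest where neither deciduous nor evergreen
   species exceed 60% canopy cover.
2. **Coarse resolution (250 m-class)** — estimate the *sub-pixel fraction*
   of each forest type by regressing, with random forests, the fractions
   observed in the fine map onto 90 seasonal features of smoothed coarse
   time series (6 signals x 5 statistics x 3 seasons), then sum the three
   type fractions into overall forest cover.

Validation uses stratified sampling: error matrices (overall accuracy,
commission, omission) for the categorical map, and

$$\mathrm{NRMSE} = \frac{\sqrt{\tfrac{1}{n}\sum_i (P_i - R_i)^2}}{\bar R}$$

plus Pearson's $r$ for the fractional maps, where $P_i$ and $R_i$ are
predicted and reference fractions and $\bar R$ the mean reference. A
comparison module harmonizes continuous tree-cover products (loss/gain
update to a target year, strict 30% thresholding, block-mean aggregation)
and quantifies their agreement across aggregation scales.

Because the real inputs are large satellite archives, the package carries a
first-class synthetic-scene generator with known ground truth; every claim
the package makes about its own method is tested against that truth.

## The synthetic scene generator

`generate_landscape()` draws a categorical class map by quantile-slicing a
smoothed Gaussian random field: white noise is smoothed with an FFT
Gaussian kernel (sigma = `patch_scale`, default 12 fine pixels ~ 360 m
patches), rank-transformed to uniform, and cut at the cumulative class
weights. This makes realised class proportions track the targets to within
one pixel's mass while keeping patch size tunable. The default class
weights (10/8/7% forest types, 8% wetland, 30% herbaceous, 27% barren, 10%
water) describe a dryland mosaic in which forest is a minority cover, so
rare-class handling is exercised by default.

Per class and signal, seasonal trajectories follow a double-logistic curve
`base + amp * (plogis(k(t - green)) - plogis(k(t - sen)))`, the standard
few-parameter phenology form. The defaults encode the structure that makes
the compositing comparison meaningful rather than decorative:

* deciduous forest has the largest NDVI/NIR amplitude, evergreen the
  smallest among forests, mixed in between (so forest types overlap on any
  single date but separate in their seasonal statistics);
* herbaceous land greens up around day 80 and senesces by day 175 (dryland
  spring flush), so at the mid-summer target day (DOY 210) it resembles
  barren land, while deciduous forest resembles wetland;
* observation noise defaults to sd 0.03 (fine reflectance), 0.02 (coarse
  indices) and 0.01 (coarse bands).

The fine stream (`simulate_fine_series()`) renders 16-day revisits by two
alternating sensors over the requested years, with spatially correlated
cloud/snow blobs (thresholded smoothed noise, per-acquisition coverage
drawn from `cloud_range`, default 5-50%) and periodic diagonal stripe gaps
for the SLC-off sensor. Values at not-clear positions are overwritten with
the sentinel −1, so any code that reads masked data produces loud, testably
wrong numbers instead of silently plausible ones. The coarse stream
(`simulate_coarse_series()`) produces two 16-day composite series offset by
8 days; each observation's signal is the area-weighted mean of the class
curves at a per-pixel random day within the period (exact linear mixing,
the assumption sub-pixel regression rests on), with MODIS-style reliability
flags. Coarse pixels nest exactly into the fine grid (`coarse_factor` = 8,
240 m) rather than at 250 m: exact nesting removes the point-spread and
resampling ambiguity that the method itself does not model.

What the generator does *not* emulate — directional reflectance, topography,
atmosphere, sensor point-spread functions, geolocation error, label noise in
training data — bounds what passing tests show: they demonstrate that the
pipeline recovers what it assumes (linear mixing, class-specific phenology),
not that it would reach the same accuracy on real archives.

## Compositing choices

`single_date_composite()` takes, per pixel and band, the clear observation
closest to the target day (default DOY 210); equidistant candidates resolve
to the earlier acquisition, so outputs are date-stable. `temporal_metrics()`
computes mean, median, sample standard deviation (n−1), and the 25th/75th
percentiles with linear-interpolation (type 7) quantiles; the convention is
fixed and documented because percentile definitions differ across software.
Pixels with fewer than `min_obs = 3` clear observations are flagged missing
rather than imputed — the multi-year epoch, not interpolation, is the
mechanism that fills gaps. Missing pixels are excluded from training and
stay missing in prediction.

One subtlety surfaced by testing: pooling three *identical* copies of a
year leaves the mean and median of every pixel unchanged, but not the
sample standard deviation (its n−1 denominator changes by a known factor)
nor the interpolated percentiles (the interpolation position `(n−1)p`
shifts). The tests assert exact invariance where it truly holds and the
exact finite-sample relationships where it does not.

## Coarse time-series preparation

`merge_terra_aqua()` interleaves the two 16-day streams into an 8-day one by
per-pixel day-of-year order; observations sharing a day are merged, and only
usable (good/marginal) observations are averaged, so reliability screening
commutes with merging. `screen_reliability()` drops no-data, snow/ice and
cloud flags.

Residual outliers are removed by `stl_outlier_removal()`. For series with
at least two observed seasonal cycles this is a robust STL decomposition
with thresholding of the remainder at `k_sd = 3` robust standard deviations
(MAD). A single-year series — the package's normal case — cannot be
decomposed that way: any attempt to manufacture cycles by tiling the year
makes every spike part of the "seasonal" component (all copies agree), so
the remainder is identically small and no outlier can ever be flagged. The
single-cycle screen therefore takes the remainder against a leave-one-out
circular running median, which is robust to isolated spikes, and removes
offenders one grid bin at a time (worst first, refitting between removals)
so that a large spike cannot drag its neighbours' remainders over the
threshold. The iteration terminates when nothing exceeds the threshold,
which also makes the screen idempotent.

`savitzky_golay_smooth()` re-implements the classic least-squares smoother
directly as local polynomial regression on the regular 8-day grid: window
of `2 * half_window + 1` points (default half-window 4, order 2 — a common
vegetation-index setting), edges handled by shrinking the window
asymmetrically, which preserves the filter's exact polynomial-reproduction
property everywhere. Gaps are bridged by linear interpolation with
nearest-value extension at the ends; pixels with fewer observations than
`poly_order + 1` are marked missing. Because the filter is a fixed linear
map on the grid, it is precomputed once as a matrix and applied to all
pixels at once.

`seasonal_statistics()` maps seasons to fixed non-leap day ranges (spring
60-151, summer 152-243, autumn 244-334) and yields the 90 features in a
fixed, documented column order (`<signal>_<season>_<stat>`).

## Fraction modelling and validation

Training blocks are chosen by greedy random thinning under a 1000 m
minimum-distance constraint (`sample_training_pixels()`): the constraint is
what matters for spatial autocorrelation, not optimal packing, so the
sampler accepts candidates in random order and reports how many fit.
Reference fractions come from counting fine land-cover pixels per coarse
block, excluding missing pixels from the denominator and dropping blocks
more than half missing. Three regression forests are fitted independently
(one per forest type, each with its own derived seed); predictions are
clipped to [0, 1] and overall cover is their sum, clipped at 1 — type
fractions cannot meaningfully exceed a pixel.

`validate_fractions()` defines its two strata on the *predicted* map
(predicted overall cover > 0 vs = 0), draws up to 1000 cells per stratum,
and reports NRMSE and Pearson r per target over the pooled sample. A
reference stratum with zero mean leaves NRMSE undefined and it is reported
as `NA` rather than silently dropped.

## Map comparison

`update_tree_cover()` applies the change-update rules (loss → 0%, gain →
100%); when both flags are set, loss wins — the conservative choice for
end-of-period cover, applied last. `threshold_forest()` is strictly
greater-than at 30%, following the forest definition. `aggregate_mean()`
drops trailing partial blocks instead of padding them, avoiding biased edge
means, and is nodata-aware. `agreement()` masks to the union of
positive-cover pixels and reports Pearson r with the OLS slope in a
configurable direction (default: second map regressed on the first),
because published slopes rarely state their regression direction.

## Problem sizes, determinism, and what the checks run

Every generator and fit takes an explicit seed and restores the caller's
RNG state, so identical inputs give bit-identical outputs. The package's
own full-scale check, `run_synthetic_study()`, uses a 512 x 512 fine grid
(64 x 64 coarse), three years of 16-day fine acquisitions, 500 training
cells per class, a 14,000-cell map-evaluation sample, 300 assessment
samples per mapped class, up to 300 fraction-training blocks and 1000
trees, and simulates fine reflectance only at the cells the study consumes
— an exact restriction that keeps one run near a minute. Across ten seeds
the study reproduces the expected qualitative behaviour: epoch metrics
classify at least as accurately as one-year metrics, which beat the
single-date composite; overall forest fraction is recovered with lower
NRMSE than any single forest type (summing removes between-type confusion);
and predicted and true overall fractions correlate above 0.9. The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
at three seeds derived from its `--seed` argument.

## Known limitations

* The phenology parameters are stipulated, not estimated from any real
  region; class separability on real imagery may be harder or easier.
* Linear mixing at the coarse scale is exact in the generator; real sensor
  point-spread functions violate it.
* The accuracy-assessment reference is the synthetic truth raster, playing
  the role of an error-free interpreter; real reference labels carry error.
* Overall-accuracy uncertainty across seeds reflects stratified-sampling
  and simulation variability, not an interpreter-agreement interval.
* Single-year coarse series limit outlier screening to the running-median
  remainder; with multi-year archives the STL path is the better screen.
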