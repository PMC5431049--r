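Package: drycover
Title: Multi-Resolution Forest-Cover Mapping from Spectral-Temporal Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mapping fractional forest cover in dryland regions by
    combining fine-resolution land-cover classification with coarse-resolution
    time-series regression. Includes a synthetic-scene generator with known
    class labels and sub-pixel fractions, spectral-temporal compositing
    (single-date and multi-year metrics), random-forest land-cover
    classification with stratified accuracy assessment, time-series
    preparation for coarse imagery (sensor merging, reliability screening,
    STL-based outlier removal, Savitzky-Golay smoothing, seasonal statistics),
    per-type random-forest regression of sub-pixel forest fractions with
    NRMSE validation, and multi-scale comparison of tree-cover maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
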