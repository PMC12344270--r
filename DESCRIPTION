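Package: rhizochron
Title: Root Growth Phenology from Minirhizotron Image Time-Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from minirhizotron scan images to community
    root-growth phenology and seasonal root-length budgets under factorial
    snowmelt and drought treatments. Covers scan preprocessing (tape masking,
    pair merging, phase-correlation registration, de-striping, contrast
    normalization), classical ridge-based root segmentation with pixel
    precision/recall evaluation, skeleton-based extraction of root length,
    diameter classes and surface area split by soil depth, growing-degree-hour
    heat sums, penalized-spline growth smoothing with 20%/80% phenology
    thresholds, seasonal and over-winter net root-length accounting, and
    block-aware permutation contrasts. Ships a synthetic-data generator that
    emulates the field experiment with known ground truth so every stage is
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    mgcv,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
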