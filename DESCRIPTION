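Package: nichetrack
Title: Maximum-Entropy Species Distribution Modeling and Habitat-Change Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for presence-background species
    distribution modeling on gridded environmental data: occurrence cleaning
    and spatial thinning, Pearson-correlation collinearity pruning, an
    L1-regularized maximum-entropy (Maxent-style) model with linear, quadratic,
    hinge, product and threshold features, k-fold cross-validation with
    ROC/AUC evaluation, percent contribution, permutation importance and
    jackknife variable diagnostics, multi-scenario projection with clamping,
    four-band habitat-suitability classification with geodesic area and
    percent-change accounting, expansion/stability/contraction change maps,
    and centroid-migration tracking across climate scenarios. Includes a
    seeded synthetic-scenario generator (spatially autocorrelated, partially
    collinear variable stacks with a known suitability surface) so the whole
    pipeline is testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    grid,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
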