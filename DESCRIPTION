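Package: oceanrange
Title: Ensemble Species Distribution Modelling and Range Maps for Marine
    Structuring Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for building global range maps of marine
    ecosystem structuring species (seagrasses, kelps, fucoids, cold-water
    corals) under present-day and Shared Socioeconomic Pathway (SSP) climate
    scenarios. Covers occurrence thinning at the estimated spatial
    autocorrelation distance, climatically structured pseudo-absence
    generation by K-means, hexagonal spatial-block cross-validation,
    monotone-constrained boosted-tree ensembles (BRT, AdaBoost, XGBoost),
    presence-only evaluation (continuous Boyce index, AUC, TSS), weighted
    ensemble projection with per-cell uncertainty, minimum-training-area
    thresholding, and depth- and dispersal-constrained binary range maps.
    Includes a synthetic-world simulator with virtual species of known
    tolerance limits so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
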