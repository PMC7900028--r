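Package: palmsdm
Title: Niche Overlap, Functional Roles and Ensemble Distribution Forecasts
    for Invasive and Native Palms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for jointly assessing environmental-niche
    overlap, functional-role overlap and ensemble species-distribution
    forecasts for an invasive and a native palm. Implements occurrence
    cleaning (temporal filtering, graticule disaggregation, distance
    rarefaction), Schoener's D niche overlap in a gridded PCA environmental
    space with a kernel occupancy density and a randomization similarity
    test, four suitability algorithms (envelope score, Gower distance,
    support vector machine, maximum-entropy-style penalized logistic),
    TSS-weighted ensemble forecasting with four binarization thresholds and
    range-overlap areas, the Sorensen beta-diversity partition of shared
    frugivore assemblages into turnover and nestedness, and a virtual-species
    simulator that provides ground truth for every stage.
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
    glmnet,
    jsonlite,
    kernlab,
    MASS,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
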