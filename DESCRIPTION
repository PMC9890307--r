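Package: podomap
Title: Ensemble Environmental Suitability and Geostatistical Burden Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage spatial pipeline for mapping a low-prevalence,
    environmentally limited disease from village-level survey data. Stage one
    fits an ensemble of species-distribution-style learners (logistic
    regression, boosted regression trees, random forest) to presence/absence
    records augmented with surface-range-envelope pseudoabsences, producing an
    AUC-weighted environmental-suitability surface with per-pixel uncertainty
    and a thresholded binary limits map. Stage two fits a binomial logistic
    geostatistical model with an exponential-correlation Gaussian process
    linking village prevalence to the suitability surface, predicts prevalence
    with exceedance probabilities on the grid, and overlays population rasters
    to estimate cases and population at risk by administrative unit. Includes
    a lightweight raster engine (nearest-neighbour alignment, Euclidean
    distance transform, D8 flow accumulation) and a seeded synthetic-landscape
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    glmnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
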