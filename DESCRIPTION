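Package: scrubBGB
Title: Below-Ground Biomass Allometry and Carbon Accounting for Scrub
    Mangrove Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the below-ground biomass (BGB) of scrub
    mangrove stands from partially excavated root systems. Provides tree
    mensuration helpers (height classes, diameter conventions, crown
    geometry, wood density), power-law and polynomial allometric model
    fitting by nonlinear least squares with adjusted R-squared, RMSE, mean
    percentage error and AIC model selection, per-tree reconstruction of
    total BGB from excavated roots plus model-predicted unexcavated roots
    and the root crown, a registry of published per-height-class model
    coefficients, stand-level biomass and carbon aggregation with
    area-scaled stocks, and a synthetic tree-population generator for
    validating the fitting machinery by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lmtest,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
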