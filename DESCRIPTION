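Package: phenodrought
Title: Drought-Response Phenomics Analysis for Augmented Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of drought-response field phenomics trials
    laid out as augmented row-column designs: generation of synthetic trials
    with known ground truth, thermal-time and FAO-56 evapotranspiration
    environment indices, crop water stress index from canopy temperature,
    beta growth-curve trait extraction from plot time series (maximum growth
    rate, canopy height, time to 75% cover, indeterminacy, senescence),
    REML mixed-model fitting with AIC model selection, BLUPs and broad-sense
    heritability, and drought-index (Yr), correlation and PCA response
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
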