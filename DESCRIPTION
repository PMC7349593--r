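Package: enose
Title: Transient Feature Extraction and Sensor-Array Reduction for
    Electronic-Nose Odor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for odor classification from metal-oxide (MOX) gas-sensor
    arrays (electronic noses). Extracts a fixed catalogue of 828 features from
    transient resistance/conductance response curves (steady-state values,
    moments, exponential-moving-average extrema, smoothed-derivative extrema,
    characteristic times, and exponential-fit parameters), selects features by
    a recursive forward wrapper and by mutual-information, Fisher-score, and
    ReliefF filter rankings under group-aware cross-validation (leave-one-group-out
    and group shuffle splits), and runs sensor-array reduction experiments over
    all sensor subsets and restricted feature sources. Includes a synthetic-data
    generator reproducing the cohort and kinetic structure of a wine-spoilage
    sensing study, so the full pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
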