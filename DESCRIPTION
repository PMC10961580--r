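Package: caseconc
Title: Case-Volume Concentration Analysis for Surgical Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how surgical case volumes are distributed
    across a workforce. Builds monthly per-provider caseload matrices from
    registry event tables, fits and compares inverse-power (Lotka-type) and
    exponential-decay frequency curves by AIC, computes concentration
    statistics (the minimal fraction of providers covering a target share of
    operations, and the generalized Price root exponent), partitions
    providers into equal-contribution volume bands and tracks them across
    periods, and generates synthetic registry data with known ground truth
    for testing, including pandemic-style shock scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
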