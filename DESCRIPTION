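Package: shockwatch
Title: Septic Shock Onset Detection and Short-Term Mortality Modelling
    from Routine ICU Time Series
Version: 0.1.0
Authors@R:
    person("Shockwatch", "Developers", email = "shockwatch@example.org",
           role = c("aut", "cre"))
Description: Rule-based detection of systemic inflammatory response
    (SIRS) episodes and septic-shock onset from irregularly sampled ICU
    vital-sign and laboratory series, extraction of 135 summary indexes
    (9 statistics x 15 variables) from the first 48 hours after onset,
    univariate survivor/nonsurvivor screening with Wilcoxon rank-sum
    tests and Benjamini-Hochberg false-discovery-rate control, and a
    7-day mortality model built by elastic-net selection with iterative
    variance-inflation-factor pruning and cross-validated AUC
    evaluation. Includes a synthetic-cohort generator that emulates the
    statistical structure of septic-shock ICU records so that every
    stage of the pipeline is testable without access to protected
    clinical data, plus a command-line interface orchestrating the full
    run with a reproducible manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
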