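Package: dcews
Title: Dynamic Complexity Early Warning Signals for Athlete Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of critical fluctuations in multivariate athlete
    monitoring time series as early warning signals of injuries. Computes
    the dynamic complexity index (the product of a fluctuation and a
    distribution measure) in an overlapping moving window, flags significant
    per-factor complexity peaks and cumulative complexity peaks via two
    one-sided z-tests, and evaluates the resulting warning signals against
    an injury log with per-player sensitivity, specificity, accuracy and a
    pooled F1 score under explicit pre-injury-window counting rules.
    Includes a synthetic cohort generator with optional injected pre-injury
    destabilization, preprocessing (inclusion criteria, imputation, session
    RPE load construction, scale normalization), a stepwise search for the
    optimal pre-injury window, and factor attribution of true-positive
    warnings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ggplot2
Config/testthat/edition: 3
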