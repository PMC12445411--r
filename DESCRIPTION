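Package: transperf
Title: Transmural Perfusion Analysis for Quantitative Myocardial Perfusion CMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing pixel-wise myocardial blood flow (MBF) maps
    from quantitative stress/rest perfusion cardiovascular magnetic resonance.
    Decomposes the contoured left-ventricular wall into endocardial and
    epicardial layers by an equidistant midventricular line constructed from
    rays cast from the blood-pool centre, parcellates each short-axis slice
    into the AHA 16-segment model with coronary-territory grouping, and
    computes layer-specific perfusion metrics: stress and rest MBF, myocardial
    perfusion reserve (MPR) per layer, endo-to-epi transmural gradients
    (sGRAD, rGRAD), and rate-pressure-product corrected quantities. Includes
    an analytic annular phantom generator and a cohort simulator for
    validation, plus cohort-level statistics (normality-gated summaries and
    group tests, 95% cohort ranges, bootstrap confidence intervals) to derive
    normative values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
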