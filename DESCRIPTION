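Package: crcalib
Title: Calibration Curves and Calibration Metrics for Competing Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graphical and numerical assessment of the calibration of
    prediction models for time-to-event outcomes subject to competing risks.
    Smoothed calibration curves are obtained by regressing the subdistribution
    hazard of the event of interest on the complementary log-log transform of
    the predicted cumulative incidence, using a Fine-Gray model with restricted
    cubic splines; the integrated calibration index (ICI), E50, E90 and Emax
    summarise the discrepancy between predicted and smoothed observed risk.
    Includes a weighted-risk-set Fine-Gray engine, Kaplan-Meier and
    Aalen-Johansen estimators, a fully specified competing-risk data simulator
    with censoring-rate calibration, and a Monte Carlo study harness for
    evaluating the calibration method under correctly and incorrectly
    specified models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cmprsk,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
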