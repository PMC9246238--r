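Package: dendroflux
Title: Individual-Tree Analysis of Stem Girth Increments Against Soil
    Moisture and Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing half-hourly dendrometer-band (dendroband)
    records from tropical forest trees together with soil moisture potential
    (SMP) and temperature series. Covers calendar alignment and short-gap
    imputation, daily mean girth and one-day girth increments, per-sensor SMP
    cleaning (offset and strict variants), dry-spell detection, running
    rainfall totals, per-mille diurnal girth-change profiles with a
    sub-period confidence envelope, a quadratic rain-shower (bark swelling)
    adjustment of increments, generalized least squares regression with
    exact-likelihood ARMA(p,q) errors, ARIMA order selection, Granger
    causality, squared-residual ACF and GARCH(1,1) non-stationarity
    diagnostics, three-way subseries recombination, and a seeded synthetic
    dendroband generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    lmtest,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
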