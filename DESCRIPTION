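Package: puptrack
Title: Movement Ontogeny of Naive Grey Seal Pups from Fastloc GPS Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing the development of movement
    behaviour in newly weaned grey seal (Halichoerus grypus) pups tracked with
    Fastloc GPS tags. Provides quality control of Fastloc fixes (satellite
    count, residual, and speed filters), haulout classification and trip
    segmentation with trip metrics, track splitting and linear interpolation
    onto a regular time grid with bathymetric covariate annotation, a
    move-persistence mixed-effects model (logit-linear covariates with
    individual random intercepts, Laplace-approximated marginal likelihood)
    with AICc model selection, one-step-ahead residuals, variance inflation
    factors and leave-one-out cross-validation, linear (mixed) models of trip
    characteristics, and a synthetic-data generator emulating tags, bathymetry
    and behaviour so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
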