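Package: fiesclim
Title: Climate Attribution of Food Insecurity via Time-Varying Panel Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds region-year panels of food-insecurity prevalence from
    individual eight-item experience-scale survey responses and monthly
    climate series, computes climate covariates (annual temperature
    anomalies against a 1981-2010 baseline, monthly anomaly bins, the
    six-month Standardized Precipitation Index and drought counts), fits
    two-way fixed-effects panel regressions with year-specific temperature
    anomaly coefficients, and quantifies the counterfactual impact of
    observed warming on food-insecurity prevalence relative to the
    historical temperature trajectory. Includes a synthetic-data generator
    with known ground truth so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
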