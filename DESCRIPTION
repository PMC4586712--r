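Package: dylld
Title: Social Disparities in Heat-Attributable Years of Life Lost
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies social vulnerability to heat in mortality time series
    via the Daily Years of Life Lost Disparities (DYLLD) index: years of life
    lost are computed from sex- and age-matched life tables, aggregated by day
    and stratified by terciles of an area-level socioeconomic indicator; the
    disparity index is related to daily mean temperature through a threshold
    (hockey-stick) quasi-Poisson model adjusted for trend, season and humidity;
    heat-attributable DYLLD rates are projected under bias-corrected
    climate-scenario ensembles and pooled across scenarios by random-effects
    meta-analysis, with meta-regression for between-city comparison. Includes a
    synthetic-data generator with known ground truth so the whole pipeline is
    testable without restricted mortality data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    MASS
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
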