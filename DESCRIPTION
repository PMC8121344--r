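Package: svycal
Title: Design Weights, Horvitz-Thompson Estimation and Weight Calibration
    for Stratified Two-Stage School Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the design-based analysis of stratified two-stage
    cluster school surveys: construction of inverse-probability design
    weights, Horvitz-Thompson estimation of totals and proportions with
    linearized (with-replacement PSU) variance, and calibration of design
    weights to known regional and national demographic margins by the
    chi-square (GREG) and raking distances.  Includes a synthetic
    school-population generator emulating a regional New Zealand secondary
    school survey frame with differential nonresponse, and a Monte-Carlo
    harness for bias, efficiency and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
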