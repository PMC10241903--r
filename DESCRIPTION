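Package: pegkin
Title: Kinematic Features and Longitudinal Statistics for Pegboard
    Accelerometry in Parkinsonism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fine-motor decline in Parkinson's disease
    and atypical parkinsonism from the Purdue Pegboard Test. Conditions
    triaxial accelerometer recordings (Hampel spike removal, zero-phase
    Butterworth band-pass filtering, decimation), extracts per-sensor
    kinematic features (standard deviation of acceleration and approximate
    entropy), and provides the longitudinal statistics used in this setting:
    one-year change scores, one-way and mixed-design analyses of covariance
    with Type III sums of squares, false-discovery-rate corrected post hoc
    comparisons, change-change correlations, and backward-elimination linear
    regression with standardized coefficients. A synthetic-data module
    generates accelerometer trials, longitudinal cohorts, and baseline
    predictor matrices with planted effects so the full pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
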