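Package: fearmotion
Title: Motion and Behavior Analysis for Instrumented Fear-Induction Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for digital phenotyping of child fear responses with a
    waist-worn inertial measurement unit (IMU). Estimates torso orientation
    (tilt and yaw) from fused accelerometer and gyroscope data, extracts six
    degree-of-freedom motion summary measures (rms accelerations and angular
    rates, tilt and yaw range of motion) over the potential-threat, startle
    and response-modulation phases of a mood-induction task, scores
    intensity-weighted behavioral fear codes with inter-rater reliability,
    and runs the standard battery of phase contrasts, modality and symptom
    correlations and diagnosis-group comparisons. Includes a synthetic-cohort
    simulator with exact forward kinematics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
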