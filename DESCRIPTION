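Package: hbgrade
Title: Objective House-Brackmann Grading from 3D Facial Landmark Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage statistical pipeline for objective grading of mimetic
    muscle function after facial-nerve injury from depth-sensor trajectories of
    21 facial points of interest. Stage 1 registers exercise recordings by
    landmark-based curve registration (dynamic time warping repetition
    detection, monotone piecewise-cubic warping functions) and computes
    per-exercise symmetry, intensity and speed indicator curves. Stage 2
    reduces each indicator curve to a health score by scalar-on-function
    logistic regression trained on the Healthy (HB1) versus Sick (HB6) extreme
    groups. Stage 3 classifies sessions into adjusted House-Brackmann grades
    {1,2,3,6} by inverse-frequency-weighted cumulative-logit (proportional
    odds) regression with stepwise AIC variable selection. Includes a
    synthetic-cohort generator with known ground truth for validation, and a
    command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    splines,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    signal
Config/testthat/edition: 3
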