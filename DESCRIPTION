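Package: riskhmm
Title: Hidden Markov Modelling of Driving Risk During Lane Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying and forecasting safe versus dangerous
    driving states during the lane-changing process from multimodal sensor
    streams. Provides a seeded generator of labelled lane-change sessions
    (R-R intervals, gaze events, vehicle traces across the car-following,
    perception, intention and execution stages), extraction of
    heart-rate-variability metrics (SDNN, CV, LF/HF via Welch's method),
    eye-movement and vehicle-dynamic indicators, two-factor variance-ratio
    and one-way ANOVA screening of features against level of service and
    driving duration, and a two-state hidden Markov model with
    Gaussian-mixture emissions fitted by Baum-Welch with log-space
    forward-backward recursions, Viterbi decoding and risk forecasting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
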