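Package: runregimes
Title: Heartbeat-Dynamics Regimes in Wearable Running Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multimodal analysis of running sessions recorded by wearable
    devices (heart rate, speed, altitude at non-uniform timestamps).
    Cleans the channels (Tanaka maximum-heart-rate zone restriction,
    z-score despiking, zero-phase Butterworth speed smoothing, altitude
    rebasing), derives the sliding-window width from the heart-rate
    autocorrelation cutoff lag with Bartlett confidence bounds, computes
    trend features (level shift plus skewness) for an external
    energy-demand proxy and for heart rate, clusters windows into four
    sign-labelled heartbeat-dynamics regimes with k-means++ and
    silhouette model selection, summarises regime frequencies, their
    temporal distribution and their relation to VO2max, and quantifies
    signal regularity via recurrence quantification analysis (recurrence
    rate and determinism). Includes a synthetic session generator with
    planted regimes and ground-truth labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
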