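Package: decnef
Title: Simulation and Analysis of Decoded fMRI Neurofeedback Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoded real-time fMRI neurofeedback studies of
    interoceptive attention. Implements the closed-loop analysis pipeline:
    block-design run schedules, percent-signal-change preprocessing of
    region-of-interest time series, spatiotemporal trial features, a linear
    support-vector-machine decoder with per-run Platt probability calibration
    and incremental retraining, neurofeedback score computation with
    condition inversion, statistically matched (yoked) sham feedback
    generation, trial-wise beta-series GLM estimation with two-fold
    cross-validated pattern classification, and heartbeat-counting
    interoceptive-accuracy statistics. A synthetic-data generator emulates
    the signal structure of such experiments (condition-specific voxel
    patterns, haemodynamic convolution, autocorrelated noise, slow drift,
    and feedback-contingent learning) so the full pipeline can be exercised
    and validated end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    RNifti,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
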