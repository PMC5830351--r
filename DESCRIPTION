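Package: condadapt
Title: Single-Trial Dynamics of Differential Fear Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising how conditioned responses adapt over the
    course of a differential fear-conditioning experiment. Implements
    single-trial (beta-series) estimation of BOLD responses from region-of-
    interest time series, Gaussian-smoothed trial-by-trial differential
    response curves with early/late contrasts, CUSUM change-point detection
    with a permutation confidence level, sliding-window representational
    dissimilarity analysis of multivoxel patterns, and stimulus-locked
    weighted-bin heart-rate deceleration curves from RR intervals. A synthetic
    data generator plants known adaptation dynamics (amplitude change points,
    decaying pattern separation, heart-rate orienting bumps) so that every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
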