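Package: fixmapr
Title: Fixation-Density Maps and Cluster-Corrected Permutation Contrasts for Face-Viewing Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing where people look on faces as a function of
    where their eyes started. Represents per-face areas of interest in degrees
    of visual angle, derives feature-anchored start positions (left, right,
    upper, lower, center), aligns faces to a common reference frame by
    translation, builds Gaussian spatial fixation-density maps (sigma = 0.3
    deg), contrasts conditions per participant, and assesses significance with
    a Monte Carlo permutation test that exchanges fixation locations only
    within matching ordinal positions, followed by nonparametric
    max-cluster-size correction for multiple comparisons. Includes a synthetic
    scanpath generator that reproduces the statistical structure of a
    start-position face-recognition experiment (toward-start first fixations,
    opposite-side later fixations, shorter first fixations, slower first
    saccades from a central start, and an equal-variance signal-detection
    old/new observer), so the whole pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
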