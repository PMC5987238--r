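Package: pulsehtn
Title: Radial Pulse-Wave Cycle Features for Hypertension-History Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 10-second single-channel radial pulse
    recordings: zero-phase Butterworth preprocessing, Shannon-energy-envelope
    plus Hilbert-transform (SEEHT) beat detection and cycle segmentation,
    shape-conditional fiducial-point detection with 20 time-domain features,
    four-level db6 wavelet packet decomposition with zero-lag higher-order
    cumulant and Shannon energy-entropy features (120 per cycle),
    correlation-based feature subset selection (CFS) with best-first search
    and occurrence-frequency voting over stratified folds, and 1-nearest-
    neighbour evaluation (accuracy, sensitivity, specificity, ROC area).
    Includes a seeded synthetic pulse-cohort generator with analytic ground
    truth emulating three blood-pressure grades and two hypertension-history
    classes in an elderly population.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
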