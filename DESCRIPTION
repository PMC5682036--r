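Package: erpstates
Title: Spatio-Temporal ERP Analysis: Microstates, Distributed Sources and
    Signal-Detection Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-density event-related potential (ERP) analysis of
    multi-group, multi-condition designs: ERP preprocessing (average reference,
    zero-phase Butterworth band-pass, decimation, spherical-spline channel
    interpolation, threshold artifact rejection, baseline correction), pointwise
    waveform statistics with minimum-duration runs, topographic microstate
    segmentation by modified k-means with cross-validation and Krzanowski-Lai
    model selection, back-fitting of template maps to individual ERPs with
    nonparametric duration statistics, a 3-shell spherical head model with
    depth-weighted minimum-norm distributed source imaging, node-wise mixed
    ANOVA with cluster-extent correction calibrated by Monte-Carlo simulation
    of smooth noise, and signal-detection (d-prime) scoring of binary appraisal
    responses.  A synthetic-data generator with known microstate structure,
    known dipolar sources and known sensitivity provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    Matrix,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
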