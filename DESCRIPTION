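Package: fgfield
Title: Figure-Ground Responsive Field Estimation from Spike Counts and
    Segmentation Labels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the spatial extent of figure and ground regions that
    drive a visual neuron's response (figure-ground responsive fields) from
    spike counts and human-style figure/ground segmentation labels.
    Implements bias-compensated spike-triggered averaging with permutation
    significance and a convergence diagnostic, recursive-least-squares
    adaptive filtering, spike-triggered covariance with an
    eigenvalue-difference significance rule, rectified linear response
    models, classical receptive field (2D Gaussian) fitting, and geometry
    metrics (PR ratio, overlap ratio, rotation and scale alignment). Ships
    a synthetic stimulus and virtual-neuron generator so every estimator
    can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
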