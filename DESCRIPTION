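Package: gazetex
Title: Texture-Based Eye-Movement Biometrics from Gaze Trajectory Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for eye-movement biometric verification and identification
    based on texture features of rendered gaze trajectories. Raw gaze
    recordings from a visual number-search task are rendered as square
    grayscale trajectory images, an 88-kernel multi-scale Gabor wavelet bank
    extracts a 176-dimensional texture descriptor per image, and probes
    (averages of several trajectory descriptors) are matched with linear
    discriminant analysis followed by one-against-one support vector
    machines. Includes a synthetic scanpath simulator with per-subject
    oculomotor profiles, I-VT fixation/saccade segmentation, three baseline
    matchers (local velocity direction histograms with GMM-UBM scoring,
    fixation density maps, and complex eye-movement statistics), biometric
    evaluation (DET/EER, CMC/Rank-k), tanh score normalization with sum-rule
    fusion, and template-aging and temporal/spatial robustness experiment
    drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
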