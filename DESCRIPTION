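Package: mcdose
Title: Monte Carlo Dose Denoising with a 3D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, training and evaluation toolkit for deep-learning
    denoising of Monte Carlo radiotherapy dose distributions. Provides a
    synthetic arc-dose simulator that pairs high-statistical-uncertainty
    ("noisy") with low-uncertainty ("clean") dose grids over CT-like phantoms,
    a natively implemented two-channel 3D U-net denoiser with the full
    training protocol (Adam, plateau learning-rate decay, early stopping,
    patch sampling and geometric augmentation), patched full-volume and
    whole-plan inference with overlap averaging, and a dosimetric evaluation
    suite (global gamma analysis, masked RMSE, improved signal-to-noise
    ratio, dose-volume histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    RNifti,
    generics,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
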