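Package: gaitemg
Title: Estimation of Lower-Limb Muscle Activity from Wearable IMU Data During Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating surface-EMG activation envelopes of nine
    lower-extremity muscles during level walking from the accelerations and
    angular velocities of four body-worn inertial measurement units (trunk,
    thigh, shank, foot). Implements the full processing chain for surface EMG
    (Butterworth band-pass filtering, rectification, low-pass linear envelope,
    stride segmentation at heel strikes, 101-point time normalization, median
    filtering and invertible min-max normalization), feedforward and long
    short-term memory neural-network regressors written in C++ (MSE loss, Adam
    optimizer, dropout, early stopping), waveform agreement metrics (nRMSE,
    Pearson r, peak-timing and peak-amplitude error), reconstruction of
    predicted envelopes back to continuous time, and a synthetic gait-data
    generator so the whole pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
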