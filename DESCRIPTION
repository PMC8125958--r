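Package: ricefusion
Title: Sensor-Array and NIR Feature Fusion for Fatty Acid Prediction in Stored Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the free fatty acid content of stored rice by fusing
    colorimetric ("olfactory visualization") sensor-array image features with
    near-infrared spectra. Implements the sensor-array image chain (median
    filtering, threshold segmentation, per-spot mean RGB differences and their
    normalization), Savitzky-Golay plus standard-normal-variate spectral
    preprocessing, principal-component feature reduction with component-count
    optimization by repeated cross-validation, a backpropagation neural-network
    regressor, monthly-stratified calibration/prediction splits, repeated-run
    validation statistics, and feature-level fusion of the optimal
    principal-component blocks. A synthetic-cohort generator emulates an
    eight-month rice storage experiment so the full pipeline can be exercised
    and tested without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
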