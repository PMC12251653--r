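Package: specshift
Title: Cross-Instrument Calibration Transfer for Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for transferring multivariate calibration models between
    near-infrared spectrometers (master/slave instrument pairs). Implements
    a multi-scale one-dimensional convolutional regression network built
    from depthwise separable convolutions, Inception-style parallel
    branches with residual connections and squeeze-and-excitation channel
    attention; a balanced distribution adaptation (BDA) fine-tuning
    objective that combines marginal and conditional maximum mean
    discrepancy terms; six layer-freezing transfer strategies; classical
    chemometric baselines (partial least squares, support vector
    regression, direct standardization, piecewise direct standardization,
    slope-and-bias correction); Kennard-Stone and SPXY sample selection
    with leave-one-out outlier screening; and a synthetic paired-instrument
    spectra simulator so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    mixOmics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    R.matlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
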