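Package: respredict
Title: Real-Time Respiratory Tumor Motion Prediction with Adaptive Neural Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time prediction of three-dimensional lung tumor motion for
    radiotherapy tracking. Implements linear (LNU), quadratic (QNU) and
    single-hidden-layer perceptron (MLP) predictors trained by batch
    Levenberg-Marquardt, an inverse-free modified Levenberg-Marquardt that
    updates every scalar weight from precomputed Jacobian columns, and
    sample-wise normalized gradient descent, inside a sliding-window engine
    that z-normalizes and retrains at every new sample and predicts a fixed
    horizon ahead in millimetres. Includes a seeded generator of
    nonstationary quasiperiodic breathing traces, 3D mean-absolute-error
    evaluation with across-seed aggregation, a configuration-grid sweep
    runner, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
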