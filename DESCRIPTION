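Package: memsgait
Title: In-Sensor Reservoir Computing for Wearable Gait-Pattern Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for gait-pattern classification
    with a micro-electromechanical (MEMS) accelerometer that doubles as a
    physical reservoir computer. Provides a synthetic generator of labelled
    foot-acceleration traces (normal, toe-out, trunk-lean and combined gait
    patterns at five treadmill speeds), an envelope-level simulator of the
    sensing proof mass coupled to a nonlinear (Duffing) beam resonator with
    time-multiplexed virtual nodes, a trained linear readout (leaky
    integration, ridge regression, moving-average smoothing and two-threshold
    decoding into four gait classes), echo-state-network and
    logistic-regression reference classifiers, and a cross-validated
    ROC/AUC evaluation protocol with confusion matrices and cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    glmnet,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
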