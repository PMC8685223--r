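Package: fogait
Title: Gait-Phase Segmentation and Freezing-of-Gait Detection from a
    Single Foot-Worn Inertial Sensor
Version: 0.1.0
Authors@R:
    person("fogait", "developers", email = "fogait@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing Parkinsonian gait from a single
    foot-mounted six-axis inertial measurement unit. Implements a causal
    rest/unrest/motion gait-phase state machine with a reactivation state
    for festinating step sequences, quaternion sensor fusion with
    strap-down integration and zero-end-velocity drift correction,
    extraction of ten spatio-temporal gait features per motion phase,
    chi-square feature ranking, SVM and AdaBoost classifiers for
    motion-phase-wise detection and prediction of freezing of gait under
    leave-one-patient-out cross-validation, a spectral freezing-index
    baseline, and a synthetic gait generator with ground-truth events for
    end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
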