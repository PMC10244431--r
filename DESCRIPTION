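Package: wearstage
Title: Wearable Sleep Staging from Photoplethysmography and Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end four-class sleep staging (Wake, N1-N2, N3, REM) for
    wrist-worn devices combining a reflective photoplethysmography (PPG)
    sensor and a triaxial accelerometer. Provides deterministic signal
    preparation (activity counts, PPG pulse and ECG QRS detection with
    motion-artifact gating, interbeat-interval and instantaneous heart-rate
    series, wearable-to-polysomnography clock synchronization), resting-period
    segmentation with a Bayesian linear discriminant, a dilated-convolution
    plus bidirectional-GRU sequence classifier with supervised training and
    multiply-accumulate operation accounting, epoch-per-epoch agreement
    statistics (Cohen's kappa, pooled confusion analytics, class merges) and a
    Hodges-Lehmann signed-rank equivalence test, together with a synthetic
    night simulator (Markov hypnograms, integral-pulse-frequency-modulation
    heart beats, rendered PPG/ECG/accelerometer waveforms with motion
    artifacts and clock skew) so the whole chain is exercisable without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    e1071,
    optparse
Config/testthat/edition: 3
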