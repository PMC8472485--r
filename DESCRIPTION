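Package: ErrPDecode
Title: Single-Trial Decoding of Error-Related Potentials with
    Calibration-Transfer Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and single-trial classification of error-related
    potentials (ErrPs) elicited by sham feedback in a brain-computer
    interface task. Provides a synthetic multi-channel EEG generator with
    participant- and day-level variability, the standard ErrP preprocessing
    chain (zero-phase Butterworth band-pass, bad-channel exclusion,
    feedback-locked epoching, amplitude-based artifact rejection,
    per-epoch baseline normalization, class balancing), waveform feature
    extraction, a scaled-conjugate-gradient trained multi-layer perceptron
    and a Ledoit-Wolf shrinkage linear discriminant classifier, and
    evaluation under within-day cross-validation, between-day transfer and
    leave-one-participant-out calibration schemes, with binomial chance
    levels, grand-average waveforms and test-retest correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
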