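Package: movintent
Title: Continuous Decoding of Pre-Movement Intention from EEG Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting the intention of self-initiated upper-limb
    movement from multichannel EEG before the movement starts. Implements
    the full offline pipeline: movement-onset detection from kinematic or
    EMG channels, epoching and z-score artifact rejection, reference-free
    spatial filtering (common average reference, small Laplacian, and
    SNR-optimal spatial filters fitted under a sum-zero constraint),
    quantification of event-related desynchronization (Morlet
    time-frequency maps with bootstrap significance) and movement-related
    cortical potentials, combined autoregressive-spectral and slow-potential
    feature extraction over sliding windows, sparse discriminant analysis
    with a feature budget, and event-based evaluation of the continuous
    decoder (ROC/AUC, correct-trial percentage, anticipation, and empirical
    chance level via label permutation). A seeded synthetic EEG generator
    with planted ERD and MRCP effects provides ground truth for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
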