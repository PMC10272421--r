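Package: eegmi
Title: Subject-Independent Motor-Imagery EEG Decoding with Filter-Bank
    CSP, GAN Augmentation and a Recurrent Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for subject-independent decoding of four-class
    motor-imagery EEG. Continuous recordings are cleaned, bandpassed
    (1-38 Hz Butterworth), z-scored against training-set statistics,
    decomposed into a 10-band filter bank and epoched into 4-s trials.
    One-versus-rest common spatial patterns are fitted per sub-band,
    log-variance features are sparsified with the LASSO, and the
    surviving spatial-filter columns form a sparse spatial filter. A
    generative adversarial network with two discriminators (one judging
    raw trials, one judging sparsely spatially filtered trials)
    synthesises subject-specific trials for augmentation, and a
    convolutional recurrent classifier trained with a center-distance
    discriminative-feature loss decodes the tasks under
    leave-one-subject-out evaluation. Includes a seeded synthetic-EEG
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
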