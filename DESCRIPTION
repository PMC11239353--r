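Package: fcdecode
Title: Connectivity-Based Decoding of Cognitive States and False-Belief
    Performance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding cognitive states (Theory-of-Mind versus Pain
    processing) and predicting false-belief task performance from regional
    BOLD time-series. Implements within-subject functional connectivity (FC)
    and leave-one-out inter-subject functional correlation (ISFC) feature
    extraction, Chebyshev spectral graph-convolutional state decoding, a
    convolutional variational autoencoder whose latent space predicts
    behavioral performance group, exact and sampled Shapley-value attribution
    of region contributions, subject-level validation protocols, and a
    synthetic BOLD cohort generator with shared stimulus-evoked, intrinsic,
    and noise signal components for fully reproducible desk-scale analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
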