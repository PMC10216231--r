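Package: deceptr
Title: Semi-Supervised Speech Deception Detection with Fused Acoustic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deceptive speech from audio with a hybrid semi-supervised
    model that fuses two views of each utterance: a three-channel log-mel
    spectrogram (static, delta, delta-delta) fed to a student/teacher
    convolutional network trained with mean-teacher consistency
    regularization, and the 384-dimensional Interspeech-2009 acoustic
    statistics vector fed to a bottleneck autoencoder. Training minimises a
    weighted sum of supervised cross-entropy on the labeled subset, a
    consistency penalty between student and teacher on unlabeled data, and
    the autoencoder reconstruction loss, with the teacher updated as an
    exponential moving average of the student. Includes from-scratch feature
    extraction (mel filterbanks, HTK-style MFCCs, autocorrelation pitch and
    harmonics-to-noise ratio, openSMILE-style functionals), a synthetic
    truth/lie corpus generator for end-to-end testing, an ablation runner,
    and tidy accessors with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
LinkingTo: Rcpp
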