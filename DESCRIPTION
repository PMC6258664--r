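Package: cervemg
Title: Cervical Spondylosis Identification from Multichannel Neck Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Screening for cervical spondylosis from six-channel neck surface
    electromyography recorded over seven standardized neck movements. Implements
    a 2949-feature extraction schema (time-domain, spectral, wavelet and
    wavelet-packet energies, autoregressive coefficients, sample entropy,
    cervical flexion-relaxation ratio, and movement-level co-activation,
    duration, energy-share and left/right symmetry features), an iterative
    random-forest top-k union feature-selection algorithm, a from-scratch
    gradient-boosted regression-tree classifier with logistic loss, and a
    subject-grouped evaluation protocol (16:4:5 split, grouped k-fold
    cross-validation, confusion-matrix metrics and ROC-AUC). A synthetic
    cohort simulator generates EMG-like multichannel recordings with tunable
    class effects so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    pROC,
    ranger,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
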