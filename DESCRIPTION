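Package: decontrast
Title: Unpaired CT Contrast Removal with a 3D Patch-Based Cycle-Consistent GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes non-contrast computed tomography (CT) volumes from
    contrast-enhanced CT using a 3D patch-based cycle-consistent generative
    adversarial network trained on unpaired cohorts, together with the
    evaluation machinery needed to audit such a model: center-weighted
    sliding-window whole-volume inference, modified Turing-test reader
    statistics with Fleiss' Kappa, a pooled deep-feature binary-classification
    harness with a shuffled-label null control, and handcrafted-radiomics
    feature-drift analysis (correlated-feature removal, Kendall rank
    selection, absolute-percentage-difference drift, ROC/AUC and bootstrap
    comparison of ROC curves). Ships a procedural chest-phantom generator
    producing unpaired contrast/non-contrast cohorts with hidden paired
    ground truth so the whole pipeline can be exercised end-to-end at desk
    scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    optparse,
    withr
Config/testthat/edition: 3
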