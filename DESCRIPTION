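Package: physiotransfer
Title: Layer-Freezing Transfer Learning for Physiological Time-Series Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cross-domain transfer learning on
    physiological signals: patient-specific seizure-state classification from
    multichannel EEG reduced by global field power, and EEG-to-ECG transfer for
    five-stage sleep scoring. Provides synthetic recording generators with
    class-dependent spectral structure, EDF and hypnogram readers and writers,
    signal conditioning (detrending, zero-phase Butterworth filtering, global
    field power), overlapping-window segmentation with epileptic-state and
    sleep-stage labeling, declarative 1D convolutional network specifications
    with closed-form shape inference, a compact seeded training engine (Adam,
    batch normalization, reduce-on-plateau, early stopping), recordwise,
    subjectwise and patient-specific split designs with stratified k-fold
    cross-validation, layer- and block-freezing fine-tuning, and confusion-matrix
    based evaluation (accuracy, sensitivity, specificity, Cohen's kappa,
    macro F1) with repeat aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
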