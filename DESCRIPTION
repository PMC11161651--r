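Package: ecgxai
Title: Dual Time-Scale Convolutional Networks for Interpretable
    Single-Lead ECG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating a two-branch ensemble of
    one-dimensional convolutional neural networks for binary
    atrial-fibrillation detection from 10-second single-lead
    electrocardiograms. One branch is constrained to a beat-scale receptive
    field (morphology), the other to a whole-recording receptive field
    (rhythm); both are designed by exactly solving the layer-wise
    receptive-field equation. The package ships a seeded synthetic ECG
    generator with ground-truth annotations, the complete preprocessing
    pipeline (Butterworth high-pass, wavelet denoising, Tukey windowing,
    min-max scaling), network training with cross-validated hyperparameter
    selection and weighted softmax averaging, thirteen post-hoc attribution
    methods (gradient family, layer-wise relevance propagation rules, deep
    Taylor decomposition, GradCAM variants, Shapley-value estimators), a
    pixel-flipping faithfulness validator with a linear-interpolation
    perturbation scheme, and template-beat relevance aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
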