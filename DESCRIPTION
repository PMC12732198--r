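Package: spatialbyol
Title: Spatially-Aware Self-Supervised Representation Learning for Retinal OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pretraining of a convolutional encoder on
    unlabeled retinal optical coherence tomography (OCT) B-scans using a
    spatially-aware variant of Bootstrap Your Own Latent (BYOL): a hybrid
    objective combining the standard pooled BYOL loss on the deepest feature
    map with a dense per-location cosine loss on a mid-depth feature map.
    Includes a two-phase fine-tuning protocol for binary classification of
    disorganization of the retinal inner layers (DRIL), inter-observer
    agreement statistics (Cohen's kappa), confusion-matrix evaluation
    metrics, Grad-CAM saliency maps, and a synthetic OCT phantom generator
    so the full pipeline runs at desk scale without external data. The
    neural-network layers (convolution, batch normalization, pooling,
    backpropagation, AdamW) are implemented with 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    patchwork,
    optparse
Config/testthat/edition: 3
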