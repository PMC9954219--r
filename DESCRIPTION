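Package: mbinet
Title: Self-Organized Operational Neural Networks for Microwave Brain Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements self-organized operational neural network (Self-ONN)
    layers whose neurons apply a learned Q-order Taylor-polynomial nodal
    operator instead of a fixed linear kernel product, together with the
    lightweight MBINet six-class classifier for reconstructed microwave
    brain (RMB) images built from them. Includes the full experimental
    protocol around the model: image loading, resizing and z-score
    normalization, a deterministic ten-transform augmentation menu,
    stratified five-fold train/validation/test planning, an Adam training
    loop with reduce-on-plateau and patience-based early stopping, weighted
    multiclass metrics, one-vs-rest ROC/AUC, a misclassification audit, and
    a seeded synthetic head-phantom image generator so the whole pipeline is
    testable at desk scale without the original dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
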