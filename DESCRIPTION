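Package: mtgnn
Title: Multi-Task Representation Learning on Attributed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint semi-supervised node classification and link prediction on
    attributed, undirected networks through a shared graph neural encoder.
    Provides graph attention (GAT) and graph convolution (GCN) encoders trained
    against a weighted combination of a cross-entropy classification loss and a
    binary cross-entropy link reconstruction loss, together with stratified
    label splits, edge-hiding splits with negative sampling, a stochastic block
    model generator for attributed benchmark graphs, ranking metrics (accuracy,
    ROC AUC, average precision), experiment drivers for label-ratio and
    loss-tradeoff sweeps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
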