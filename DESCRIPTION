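Package: doubletvae
Title: Doublet Detection for Single-Cell RNA-Seq via a Cluster-Aware
    Variational Autoencoder and Positive-Unlabeled Bagging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates doublets (two cells sharing one barcode) in droplet
    based single-cell RNA-seq count data. Artificial doublets are simulated
    by summing randomly paired cell profiles and rescaling to realistic
    library sizes; a preliminary doublet score is derived from the fraction
    of simulated doublets among each barcode's nearest neighbors; a
    cluster-aware variational autoencoder learns a low-dimensional embedding
    of real and simulated cells jointly; positive-unlabeled bagging with a
    logistic-regression classifier converts the embedding into per-barcode
    doublet scores; and a composite cost balancing false-negative rate,
    false-positive rate and a penalty on the deviation from the expected
    doublet count selects the threshold for binary doublet calls. Includes
    a negative-binomial synthetic data generator with ground-truth doublet
    labels, evaluation utilities (average precision, k-nearest-neighbor
    label preservation, neighborhood singlet fractions) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse,
    withr
Config/testthat/edition: 3
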