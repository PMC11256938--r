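Package: zinbmix
Title: Deep Generative Clustering of Single-Cell RNA-Seq Counts with a
    Gaussian-Mixture Latent Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-based clustering and batch-effect correction for
    single-cell RNA-seq count matrices. Cells are embedded by a variational
    autoencoder whose observation model is the zero-inflated negative
    binomial distribution and whose latent prior is a Gaussian mixture with
    identity covariances, so cluster structure is part of the generative
    model rather than a post-hoc step. Batch labels condition both encoder
    and decoder, removing technical variation from the latent space.
    Training interleaves reparameterized stochastic gradient ascent on the
    evidence lower bound (hand-written backpropagation and Adam) with EM
    updates of the mixture weights and means. Includes a splat-style count
    simulator with logistic dropout and batch factors, built-in and
    Louvain clustering of the latent encodings, ARI/NMI and a KNN-region
    KL divergence of batch mixing, Matrix Market and 10x-style readers,
    and a command-line interface.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Encoding: UTF-8
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
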