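Package: fumap
Title: Fuzzy Cross-Entropy Losses for UMAP-Style Low-Dimensional Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A full-batch, sampling-free implementation of the UMAP family of
    nonlinear dimensionality reduction methods. Builds the fuzzy weighted
    k-nearest-neighbour graph of a high-dimensional dataset (smooth k-NN
    distance calibration, exponential memberships, probabilistic t-conorm
    symmetrization), fits the low-dimensional similarity curve for a given
    min_dist, and optimizes one of four fuzzy information-discrimination
    losses (the reduced-repulsion cross entropy of the reference UMAP,
    plain fuzzy cross entropy, symmetric fuzzy cross entropy, and modified
    fuzzy cross entropy) with analytically derived gradients and full-batch
    Adam from a spectral (Laplacian eigenmap) initialization. Includes
    synthetic dataset generators (Gaussian blobs, half moons, concentric
    circles), a bundled 8x8 handwritten-digits dataset, and quantitative
    structure-preservation metrics (k-NN recall, trustworthiness, global
    distance rank correlation, cluster-recovery ARI).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    minpack.lm,
    mclust,
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
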