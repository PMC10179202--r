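Package: cryohetero
Title: Unsupervised Classification of Heterogeneous Cryo-EM Projection Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying heterogeneous single-particle cryo-EM
    projection images without templates or prior orientation knowledge.
    Implements an end-to-end pipeline: simulation of noisy projection stacks
    from 3D density maps (MRC) or built-in phantoms with uniform SO(3)
    orientations and variance-ratio SNR noise; image preprocessing (Fourier
    cropping to 64x64, per-image normalisation); feature extraction with a
    multi-layer-perceptron autoencoder trained iteratively or a residual
    convolutional autoencoder trained in a single pass; UMAP reduction of the
    latent variables to 2D; shared-nearest-neighbour graph construction with
    an adaptive neighbourhood size and normalized spectral clustering;
    matched classification accuracy against ground truth; and direct-Fourier
    reconstruction of per-class density maps scored by Fourier shell
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
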