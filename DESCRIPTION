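Package: hierct
Title: Hierarchical Learned Reconstruction for Parallel-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying tomographic image reconstruction as a learned,
    hierarchically decomposed domain transform. The sinogram-to-image mapping of
    two-dimensional parallel-beam computed tomography is broken into a sequence
    of partial-line-integral representations with progressively finer depth
    resolution and coarser angular sampling, each transition implemented as a
    sparse-connection linear network layer. The package provides an exact
    ray-tracing forward projector, filtered backprojection onto isotropic and
    anisotropic grids, stage-schedule planning, sparse-layer construction and
    parameter accounting, the noise-pattern training protocol (stage-wise
    pretraining followed by end-to-end training with single-random-layer
    updates, and nonlinear refinement on phantom images), analytic ellipse
    phantoms, and image-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
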