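Package: SliceOT
Title: Spatial Transcriptomics Slice Integration with Graph Attention and Unbalanced Optimal Transport
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint alignment and integration of spatial transcriptomics slices.
    A graph attention autoencoder with tied encoder/decoder weights embeds spots
    from multiple slices into a common latent space while an unbalanced entropic
    optimal transport plan, solved by inexact proximal-point Sinkhorn iterations,
    provides a probabilistic spot-to-spot alignment. The plan guides rigid 2D
    registration (weighted SVD Procrustes/ICP) and 3D stacking of slices.
    Includes readers and writers for common spatial formats (h5ad, MatrixMarket,
    CSV), alignment and batch-mixing metrics, and a synthetic-slice generator
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    rhdf5,
    mclust,
    cluster,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
biocViews: Spatial, Transcriptomics, BatchEffect, DimensionReduction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
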