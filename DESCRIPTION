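Package: ssre
Title: Single-Cell Clustering by Sparse Subspace Representation and
    Similarity Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-type identification for single-cell RNA-seq expression
    matrices by similarity learning. Each cell is expressed as a sparse
    linear combination of the other cells (sparse subspace representation,
    solved by an alternating direction method of multipliers), the learned
    affinity is refined by Laplacian-score gene selection under four
    similarity graphs and by a common-neighbor (weighted Adamic/Adar)
    imputation of missing edges, and cells are grouped by spectral
    clustering with eigengap estimation of the number of clusters.
    Includes a Splatter-style count simulator with calibrated dropout,
    clustering evaluation metrics (NMI, ARI), Kruskal-Wallis differential
    expression screening, and similarity-based 2D embedding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    Rtsne,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
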