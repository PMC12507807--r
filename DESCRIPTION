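Package: silsweep
Title: Silhouette-Guided Selection of Single-Cell Clustering Resolution
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects the clustering resolution for single-cell RNA-seq data
    by sweeping a grid of resolution values over graph community detection
    (Leiden or Louvain) and choosing the resolution that maximizes the mean
    silhouette score of the resulting partition in principal-component space.
    Ships the surrounding pipeline stages: quality-control filtering on UMI
    totals and mitochondrial fraction, depth normalization, highly-variable
    gene selection, PCA, k-nearest-neighbor graph construction, marker-driven
    cluster annotation, Ward dendrograms of cluster centroids, condition-wise
    cell-type composition tables, and a negative-binomial count simulator
    with ground-truth cell types for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    ape,
    cluster,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
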