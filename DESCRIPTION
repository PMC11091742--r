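Package: cascc
Title: Co-Expression-Assisted Single-Cell Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters single-cell RNA-seq data using gene co-expression
    signatures discovered by an adaptive attractor algorithm. An initial
    graph-based clustering proposes marker-gene seeds; attractor signatures
    converged from those seeds drive feature selection, determine the number
    of clusters K, and seed a deterministic K-means step at the cells that
    maximally express each signature. Also provides partition-agreement
    metrics (adjusted Rand index, adjusted and normalized mutual
    information), cluster-number accuracy scores (absolute log-modulus,
    deviation score), silhouette evaluation of 2D embeddings, and a
    negative-binomial synthetic-data generator with planted cell types and
    co-expression modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    cluster,
    splines,
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
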