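Package: snealign
Title: Soft Alignment of t-SNE Embeddings Across Single-Cell Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns 2-D t-SNE embeddings of multiple single-cell samples
    (patients, modalities, time points) without modifying the samples'
    feature space. Per-cell-type centroids are Procrustes-aligned in PCA
    space to fix each sample's embedding initialization, and a
    center-attraction force term added to the t-SNE optimization pulls
    shared cell-type centers toward a reference, yielding comparable
    embeddings that retain each sample's independent local structure.
    Includes matched-cluster annotation via k-means plus mutual nearest
    neighbors when cell-type labels are absent, greedy selection of
    primary and secondary reference samples, an alignment score and a
    k-nearest-neighbor locality-preservation metric, and a synthetic
    multi-sample Gaussian-mixture generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    rhdf5,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
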