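Package: TrajEnsemble
Title: Ensemble Pseudotime and Fine-Tuned Cluster Trees for Single-Cell
    Trajectory Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trajectory inference for single-cell RNA-seq expression
    matrices. Expression is preprocessed by iterated base-2 log rescaling
    and gene quality control, projected onto pathway gene sets by
    per-pathway factor analysis, and embedded in a low-dimensional latent
    space. Pseudotime is inferred as an ensemble over clusterings at
    multiple resolutions: each clustering contributes a per-cell distance
    from the start cluster's center, and the per-resolution vectors are
    averaged. The cluster-level trajectory is a minimum spanning tree on
    cluster centers, rooted at the start cluster and fine-tuned so that
    mean pseudotime never decreases from a vertex towards its
    descendants. Includes a synthetic trajectory simulator, an evaluation
    routine scoring pseudotime against developmental stage labels, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    optparse,
    cluster,
    withr,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
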