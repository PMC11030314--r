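Package: microtraj
Title: Microglia Aging Trajectories from Single-Cell Counts to Gene Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to reconstruct an aging trajectory in hippocampal
    microglia from single-cell RNA-seq count matrices and to quantify its
    gene-expression programs. The pipeline covers quality-control
    filtering, log normalization, variable-gene selection and PCA, kNN
    cell graphs with Louvain clustering, principal-curve pseudotime with
    a designated young root and terminal branch splitting, discovery of
    trajectory-dependent gene modules by Moran's I graph autocorrelation
    followed by Louvain community detection on gene correlation graphs,
    and projection of perturbation contrasts onto modules via per-module
    log2 fold changes with one-sample t-tests. A negative-binomial
    simulator with planted module structure provides ground truth for
    recovery tests, and formula-defined image-quantification operators
    score puncta-based microglial activation and RNAscope counts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
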