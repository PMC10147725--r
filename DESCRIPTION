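Package: wmconn
Title: Weighted White-Matter Connectome Topology, Inference and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for weighted white-matter structural brain
    networks built from tractography connection-probability matrices. Provides
    thresholded weighted graph construction over a consensus threshold grid,
    global and regional topological attributes (weighted clustering, weighted
    characteristic path length, Louvain modularity, cluster-corrected
    small-worldness against degree-preserving rewired nulls, nodal efficiency
    and a composite hubness score), threshold-AUC feature integration,
    permutation-based general linear model group inference with Cohen's d and
    Pearson partial correlations, the network-based statistic (NBS) with
    max-component-size family-wise error control, and a LASSO plus linear SVM
    classifier with repeated stratified cross-validation, Cohen's kappa and a
    label-permutation significance test. Includes a synthetic cohort generator
    with injectable group contrasts so the whole pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    glmnet,
    e1071,
    pracma,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
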