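Package: decontox
Title: Immune-Cell Deconvolution and Trafficking Stratification for Toxicogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reference-based immune-cell deconvolution of bulk liver
    transcriptomes and downstream stratification of hepatotoxic compounds by
    estimated immune-cell trafficking. Builds a cell-type signature matrix from
    sorted-cell reference profiles by fold-change marker selection, estimates
    per-sample cell-type scores by elastic-net regression, z-scores estimates
    against matched vehicle controls, combines six low-dimensional embeddings of
    compound trafficking features into a spectral meta-distance for hierarchical
    clustering, and characterizes clusters with single-sample gene set
    enrichment (ssGSEA) and rank-based discriminative-term tests. Includes a
    synthetic-data generator emulating a multi-compound, multi-time-point
    toxicogenomics study with known cell proportions and planted cluster
    structure, so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rtsne,
    uwot
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
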