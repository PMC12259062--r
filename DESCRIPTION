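Package: surfmed
Title: Transport Trios and Mediation Models for Surface-Protein Regulation in CITE-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the transcription of intracellular-transport (ICT)
    genes shapes cell-surface protein abundance beyond the transcription of the
    protein's own coding gene, and how that surface abundance mediates a disease
    phenotype. From paired RNA/ADT single-cell matrices it builds (protein,
    coding gene, ICT gene) trios, fits per-trio mixed-effects regressions with a
    sample random intercept to call putative transport trios at a false discovery
    rate threshold, runs single-exposure linear mediation with Sobel or bootstrap
    inference, fits an L1-regularized multi-exposure mediation model with BIC
    selection along a lambda path, and exports the implied signed regulatory
    network. A synthetic-data generator with planted effects makes every step
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    methods,
    tools
Suggests:
    glmnet,
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
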