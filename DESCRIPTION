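Package: coexprog
Title: Co-Expression Modules, Network Integration and Prognostic
    Signatures for Tumor Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a weighted gene co-expression
    analysis workflow for staged tumor expression data: probe-to-gene
    collapsing and coefficient-of-variation screening, signed weighted
    co-expression networks with topological overlap, module detection and
    eigengene-trait correlation over an ordinal disease-progression
    gradient, integration of cancer-related modules with a protein-protein
    interaction network via a per-gene neighborhood over-representation
    (Fisher exact) screen, expression-profile clustering, generic
    over-representation analysis against GMT gene sets, and a prognostic
    signature built from univariate Cox filtering, Kaplan-Meier/log-rank
    comparison and cross-validated LASSO-Cox selection.  Ships a synthetic
    data generator (modular expression over ordinal stages, scale-free
    interaction graphs with planted neighborhood enrichment, and
    proportional-hazards survival times) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    glmnet,
    igraph,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
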