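Package: omicvar
Title: Variance Decomposition and Delta-Network Analysis for Repeated-Measures Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for panel studies that profile several omics layers in the
    same individuals at repeated visits. Per-feature linear mixed models
    partition variance into intra-individual, inter-individual and cohort
    components and attribute variance to biological and sampling traits, with
    a collinearity guard. Between-visit change scores of high intra-variability
    features feed a shrinkage partial-correlation Gaussian graphical model with
    an empirical-null false discovery rate for edge calling, connected-component
    summaries and network export. Includes quality-control filters (call rate,
    probe reliability, coefficient of variation, limit of detection, linear
    range), plate centering, protected residualization against nuisance
    covariates, CpG-context enrichment tests, and a synthetic multi-omics study
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    lme4,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
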