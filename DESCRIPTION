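Package: plasmasig
Title: Plasma Proteome Progression Signatures with Network and Survival
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving metastasis-progression protein signatures
    from multi-cohort pooled plasma proteomics. Implements peptide-rule
    filtering and paired differential testing within cohorts, loess
    normalization and four-cohort fold-change concordance selection,
    protein-protein interaction subnetwork construction with hub
    augmentation, topology metrics and hierarchical layer assignment,
    hypergeometric gene-set enrichment, cross-species (human/mouse/cell
    line) signature refinement, and evaluation of a mean-expression risk
    score by Kaplan-Meier, log-rank and Cox proportional hazards models.
    A synthetic-data module emulates every input (peptide-level cohort
    tables, mouse longitudinal plasma, cell-line spectral counts,
    scored interaction edges, and a survival cohort) with planted ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
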