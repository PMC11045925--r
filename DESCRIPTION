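Package: deorphanr
Title: Simulation-Backed Analysis of Transporter Deorphanization Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for assigning substrates to orphan solute
    carriers. Implements an exometabolome differential screen (per-compound
    log2 fold change with a coefficient-of-variation gate), import/export
    calling for heterologously expressed transporters assayed in Xenopus
    oocyte pools against GFP-only controls, classification of significant
    importers as concentrative or equilibrative against the medium
    concentration with endogenous-background correction, and growth-phenotype
    analysis (maximum specific growth rate, maximum OD, four-parameter
    logistic LC50). Ships seeded synthetic-data generators for all three
    assay types so every stage has a ground-truth recovery test surface, and
    a pipeline orchestrator with schema validation and a combined report.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
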