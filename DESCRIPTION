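Package: panelign
Title: Cross-Species Co-Expression Panel Design and Model Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Designs module-anchored gene-expression panels from human brain
    co-expression modules and evaluates mouse models against human disease
    signatures. Ranks genes within each module by a PCA-weighted score,
    filters to expressed one-to-one mouse orthologs, designs probe pairs with
    nearest-neighbor thermodynamics and in-silico cross-hybridization and
    panel interaction screens, normalizes counts by housekeeping geometric
    means, performs moderated-t differential expression, correlates mouse and
    human log fold changes per module, and runs hypergeometric and GSEA
    enrichment. Includes seeded synthetic-data generators with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'conservation.R'
    'correlation.R'
    'enrichment.R'
    'expression_stats.R'
    'io.R'
    'panel_qc.R'
    'prioritization.R'
    'probe_design.R'
    'simulate.R'
    'thermo.R'
    'utils.R'
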