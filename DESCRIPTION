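Package: SynergyScreen
Title: Combination-Index Scoring and Pan-Cancer Prioritization of Drug
    Combination Screens
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing epigenetic-inhibitor x PARP-inhibitor
    combination screens. Implements median-effect dose-response fitting and
    Chou-Talalay combination-index (CI) scoring with synergy classification,
    a five-feature clinical priority score for ranking inhibitor panels, a
    formula-defined siRNA impact score combining transcriptional repression
    with PARP-inhibitor sensitization, directional pan-cancer meta-analysis
    of differential expression and survival (one-sided tests combined by
    Fisher's method, Cox proportional-hazards z-statistics), per-cancer-type
    dependency summarisation, hallmark-signature correlation ranking,
    Fisher's-exact enrichment testing with FDR control, and rule-based
    assembly of BRCAness gene catalogs from multi-source gene lists. A
    seeded synthetic-data generator with planted ground truth emulates every
    input the pipeline consumes, so each stage has a recovery-style test
    surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Pharmacogenomics, GeneExpression, Survival,
    StatisticalMethod
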