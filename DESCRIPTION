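Package: abeSelect
Title: Spectral-Count Selection of S-Acylated Proteins from Acyl-Biotin
    Exchange Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying S-acylated (palmitoylated) proteins from
    paired hydroxylamine-treated (+Hyd) and control (-Hyd) acyl-biotin
    exchange (ABE) enrichment experiments analysed by label-free spectral
    counting. Implements probability filtering of peptide-spectrum matches,
    shared-peptide exclusion, per-run spectral count normalization,
    +Hyd/-Hyd enrichment ratios, and a replicate-aware decision table that
    assigns proteins to high and medium confidence tiers with a full rule
    trace. Includes a seeded synthetic PSM generator with planted protein
    classes for validating the selection procedure, recovery scoring
    against the planted truth, and descriptive cross-tabulations of
    external annotations (kinase families, transmembrane domains,
    predicted acylation sites, detergent-resistant membrane overlap).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
biocViews: Proteomics, MassSpectrometry, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
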