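Package: MytilusPanel
Title: Diagnostic SNP Marker Discovery and Hybrid Classification for the
    Mytilus Species Complex
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering species-diagnostic SNP markers from
    RAD-seq genotype data and for multilocus classification of blue mussels
    (Mytilus edulis, M. galloprovincialis, M. trossulus) as pure species,
    F1 hybrids or introgressed composites. Implements the two-tier
    informative/diagnostic locus filter, a KASP-style assay feasibility
    screen, PCA and discriminant-loading marker ranking, single-locus
    Me15/16 amplicon-size genotyping, panel-based genotype classification
    with per-site summaries and diagnostic-allele ancestry fractions, and a
    fully seeded synthetic cohort generator with truth labels for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    MASS,
    vcfR,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    cluster,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SNP, Genetics, PopulationGenetics, VariantDetection, Classification
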