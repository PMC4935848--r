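Package: poolscreen
Title: Pooled Exome Screening for Low-Frequency Disease Risk Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control screens that exome sequence pooled DNA
    samples to find low-frequency risk variants. Implements minor-allele
    frequency estimation from pooled read counts, a multi-reference enrichment
    filter cascade with a full audit trail, two-round genotype validation,
    PLINK-style allelic case-control association against a merged population
    reference (with Hardy-Weinberg exact tests, differential-missingness and
    sample QC), additive-model quantitative-trait regression, EM-based linkage
    disequilibrium statistics, and a Genetic Power Calculator style
    discrete-trait power model. A synthetic-data generator emulates the full
    study design (pooled cases, technical-control pools, a large unselected
    reference cohort) so the pipeline is testable end to end without
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
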