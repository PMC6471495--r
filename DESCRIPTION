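Package: racepop
Title: Population Structure and Race-Diagnostic SNP Markers for Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Racepop", "Developers", email = "racepop@example.org", role = c("aut", "cre"))
Description: Analysis of biallelic SNP genotype panels from germplasm
    collections structured into ecological races (e.g. Mexican, Guatemalan and
    West Indian avocado) and their interracial hybrids. Provides genotype
    matrix input/output (minimal GT-only VCF and dosage TSV dialects), a
    Balding-Nichols multi-race panel simulator with planted race-diagnostic
    loci, locus completeness and sliding-window LD pruning filters, per-locus
    and per-population diversity statistics (MAF, Ho, He, Nei's unbiased gene
    diversity, Shannon's I, PIC), identity-by-state distances with UPGMA trees
    and Newick export, principal coordinate analysis, two-level AMOVA with
    permutation tests, supervised ancestry-proportion estimation with the
    Evanno delta-K utility, three-step discovery of race-diagnostic SNP loci,
    KASP allele-specific assay construction, and race classification of
    unknown accessions, plus a pipeline driver and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
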