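Package: famgbs
Title: Family-Based Genetic Burden Scores and Gene-Level DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for within-family candidate-gene analysis in
    multi-generational pedigrees: a PLINK-dialect pedigree model with
    generation assignment, blood-relative subsetting and Mendelian
    consistency checking; risk-allele burden scoring (an unweighted
    Genetic Burden Score, GBS) over a designated SNP panel extracted from
    candidate-gene regions with reproducible QC filtering; APOE
    epsilon-diplotype calling from rs429358/rs7412; gene-level CpG
    methylation summaries with probe filtering and genotype-methylation
    correlation; within-family descriptive statistics (per-generation
    summaries, sibling discordance, epsilon4-carrier comparison,
    intraclass correlation, generational trend); and a seeded synthetic
    family generator (founder haplotypes with linkage disequilibrium,
    meiosis with recombination, beta-valued methylation) so every stage
    is testable without restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
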