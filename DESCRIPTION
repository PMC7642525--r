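Package: twinseg
Title: De Novo Variant Discovery in Discordant Monozygotic Twin Quartets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quartet families of monozygotic twins
    discordant for a congenital phenotype (affected twin, unaffected co-twin,
    two parents). Identifies post-twinning de novo single-nucleotide and indel
    candidates by family segregation plus functional-class and population
    minor-allele-frequency filters, verifies monozygosity by genotype
    concordance, calls copy-number variants from targeted read depth against a
    within-family reference of healthy members, performs cross-family
    recurrence analysis of variants, genes and CNV-affected genes, and scores
    pathway enrichment of candidate genes with an upper-tail hypergeometric
    statistic with Benjamini-Hochberg correction. Includes a synthetic-cohort
    generator with planted ground truth so every stage is testable without
    access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
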