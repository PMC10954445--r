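Package: nrskit
Title: Discovery, Genotyping and Population Genetics of Nonreference Sequences
Version: 0.1.0
Authors@R:
    person("NRS", "Toolkit Developers", email = "nrskit@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for nonreference sequences (NRSs):
    DNA present in individual genomes but absent from a linear reference.
    Provides a seeded simulator of reference genomes and population
    assembly panels with planted insertion events; extraction of
    unaligned segments from contigs with depth, satellite and
    contamination filters; flank-based anchoring of insertions to the
    reference with permutation hotspot detection; merging of per-sample
    calls into a nonredundant population catalogue; presence/absence
    genotyping with Hardy-Weinberg and trio Mendelian validation; and
    the downstream inference layers: allele-frequency classes, growth
    curves, PCA, Hudson FST and the population branch statistic with
    downsampling consensus, cis-eQTL and GWAS association models, and
    linkage disequilibrium with phenotype-associated SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
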