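Package: rohscan
Title: Runs of Homozygosity Detection, Genomic Inbreeding and ROH Islands
    for SNP-Array Cohorts
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for runs-of-homozygosity (ROH) analysis of
    diploid autosomal SNP-array genotypes in structured livestock cohorts.
    Reads and writes PLINK text (PED/MAP) and binary (BED/BIM/FAM) genotype
    data; applies call-rate, minor-allele-frequency and Hardy-Weinberg
    exact-test quality control; detects ROH with a PLINK-style sliding-window
    scanner under seven calling criteria including the Lencz minimum-SNP
    rule; summarises ROH by physical length class; estimates per-individual
    genomic inbreeding as F_ROH and excess-homozygosity F_HOM with their
    Pearson correlation; calls ROH islands from per-SNP ROH incidence and
    annotates them against BED/GFF3 feature intervals; builds a GCTA-style
    genomic relationship matrix with principal component analysis; and
    simulates breed-structured cohorts with planted autozygous tracts and
    island loci as exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
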