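Package: guenomix
Title: Comparative Population Genomics of Introgression, Inbreeding and
    Mutation Load in Primates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for the comparative-genomic analysis of closely
    related primate lineages from multi-sample variant calls: genotype-level
    depth and allele-balance filtering, genome-wide and per-impact-category
    heterozygosity, plink-style runs-of-homozygosity calling with
    accessible-genome normalisation, derived-allele mutation-load ratios,
    ABBA-BABA D-statistics with weighted block-jackknife standard errors,
    windowed f_dM introgression landscapes with cross-lineage comparison,
    detection of convergent amino-acid substitutions in codon alignments,
    and Fisher's exact gene-set overlap tests. Includes a truth-known
    synthetic-data generator (structured coalescent with an admixture
    pulse, planted autozygous tracts, impact-labelled derived alleles and
    planted convergent codon columns) so every stage can be validated
    against known simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
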