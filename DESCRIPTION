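Package: relociate
Title: Regulatory Re-Prioritization of GWAS Loci with QTL, Allelic
    Imbalance and Linkage-Disequilibrium Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting disease GWAS loci with tissue-specific
    regulatory evidence. Expands GWAS-annotated candidate gene lists by
    exact matching of marker variants against cis-eQTL and cis-sQTL
    catalogues and by strand-agnostic transcript overlap, and classifies
    each locus into agreement tiers. Assesses allelic expression imbalance
    at heterozygous marker sites with an LD-stratified control that
    separates cis-regulatory effects from systematic count bias.
    Enumerates independent cis-eQTL signals from the relationship between
    per-variant effect sizes and linkage disequilibrium with the lead
    eQTL, compares nested generalized linear models for expression and
    disease endpoints by likelihood-ratio testing, and computes
    ANOVA-based eQTL detection power under Hardy-Weinberg genotype
    weights. A deterministic synthetic-data generator (founder-mosaic
    haplotypes, planted additive cis effects, binomial allelic counts
    with reference bias) makes every stage testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
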