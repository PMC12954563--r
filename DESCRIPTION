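Package: spetkit
Title: Design and Analysis of Targeted Genotyping (SPET) Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to design single-primer enrichment (SPET) targeted
    genotyping panels with minimal ascertainment bias and to quality-control
    and analyse the resulting genotype data. Builds k-mer mappability tracks
    over a reference genome or transcriptome, detects low-repetitiveness
    regions eligible for random target sites, assembles probe panels mixing
    random and known targets, removes UMI-tagged PCR duplicates, classifies
    working probes, applies a full hard-filter / HDplot / genotype-level
    filtering cascade to joint-genotyped VCFs, and computes population-genetic
    summaries: observed and expected heterozygosity, Weir-Cockerham FST with
    bootstrap confidence intervals, missing-data-aware nucleotide diversity
    using invariant sites, KING-robust kinship, technical-replicate
    concordance, and species-diagnostic marker discovery. A synthetic-data
    generator (genomes with repeat families and gene models, error-free read
    pairs, UMI-tagged capture reads, island-model genotype matrices with known
    differentiation) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
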