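Package: histoneBurden
Title: Mutation Burden and Mutational Processes in Redundant Histone Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of somatic mutation burden in redundant gene families,
    built around the histone gene complement. Provides a redundancy-aware
    per-protein mutation-rate statistic that pools mutation counts and coding
    length across all genes encoding one protein, rank-based group comparisons
    with Benjamini-Hochberg control and fold-change reporting, chi-squared
    homogeneity tests across genes encoding a common protein with a Monte-Carlo
    fallback for sparse tables, SBS96 trinucleotide mutational-profile
    construction from MAF-style variant tables, maximum-likelihood signature
    refitting against a COSMIC-layout catalog with bootstrap confidence
    intervals and etiology merging, mutation co-occurrence testing, and
    covariate correlation. A fully synthetic cohort generator with known
    ground truth (reference sequences, signature-driven mutations, gene-level
    rate multipliers, hypermutators) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
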