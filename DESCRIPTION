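Package: ssrflank
Title: Decomposition and Population-Genetic Analysis of Microsatellite
    Amplicon Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sequenced simple sequence repeat (SSR,
    microsatellite) amplicons. Decomposes each sequenced allele into four
    components of variation (amplicon size, repeat counts per block, flanking
    region haplotype, whole-amplicon sequence), codes indel runs as single
    mutational events, flags imperfect repeats, and classifies size homoplasy.
    Provides per-component diversity summaries (Nei's gene diversity, SNP
    density), exact tests of linkage disequilibrium between flanking-region
    polymorphisms (full enumeration and a Markov chain Monte Carlo sampler),
    allele-level distance matrices with Mantel concordance tests, AMOVA-based
    population differentiation statistics (FST, RST, NST with an optional
    repeat-step weight), UPGMA consensus population trees, and a coalescent
    simulator of joint SSR and flanking-region evolution so that every stage
    can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
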