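Package: icecensus
Title: Detection and Comparative Analysis of Integrative and Conjugative
    Elements in Closely Related Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico census pipeline for integrative and conjugative
    elements (ICE), actinomycete ICEs (AICE), integrative mobilizable elements
    (IME) and their decayed derivatives in populations of closely related
    bacterial genomes, modeled on linear-chromosome Streptomyces. Detects
    signature proteins (integrase, relaxase, coupling protein, VirB4, TraB,
    Rep) by position-specific profile scoring and similarity search, delimits
    elements by their flanking direct repeats (target-site duplications),
    classifies them from the signature-module content, clusters TraB proteins
    into families at an amino-acid identity threshold, profiles cargo genes
    and pseudogenization, and performs cross-strain comparative analyses
    (presence/absence matrices, accretion, core-versus-arm localization,
    Fitch small parsimony on a strain cladogram). Includes a seeded synthetic
    population generator that plants elements with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
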