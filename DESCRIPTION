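Package: balancerSV
Title: Split-Read Detection and Design of Engineered Balancer Chromosome
    Rearrangements
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects large chromosomal rearrangements (inversions, reciprocal
    translocations, deletions, insertions, duplications) from soft-clipped
    short single-end reads by exact 16-mer seeding with an Aho-Corasick
    automaton followed by Smith-Waterman realignment of the clipped tails,
    split-read classification, control subtraction and normalized-depth /
    depth-ratio filtering. Includes a seeded simulator of rearranged genomes
    with mapper-emulated alignments, CRISPR sgRNA site scanning and chimeric
    homology-arm targeting-vector construction for engineering balancer
    chromosomes, and screening statistics (efficiency ratios, Fisher exact
    test, homologous-recombination versus end-joining breakpoint repair
    classification).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    stringi,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
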