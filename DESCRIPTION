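Package: sketchasm
Title: Hierarchical Long-Read Assembly with Weighted MinHash Overlapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale overlap-layout-consensus assembler for noisy
    single-molecule long reads. Implements adaptive tf-idf weighted MinHash
    sketching for all-vs-all overlap candidate detection, bottom-sketch
    overlap extent and Mash-distance error estimation, hierarchical read
    correction via a directed acyclic graph consensus, overlap-based
    trimming with hairpin and chimera detection, two-pass overlap error
    adjustment, and greedy best-overlap-graph contig construction with
    automatic error-rate thresholding (median + 6 MAD), per-contig error
    profiles, statistical repeat separation and GFA 1.0 assembly-graph
    output. Includes a seeded synthetic-data generator (genomes with
    divergent multi-copy repeats, log-normal read lengths, tunable error
    mix) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
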