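Package: cnvhmm
Title: Copy Number Variant Calling from Low-Pass Sequencing with a
    Depth and Mate-Pair Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls medium-size deletions and other copy number variants
    from low-pass whole-genome resequencing alignments using a hidden
    Markov model whose emissions jointly model per-position read-start
    depth (Poisson, GC-adjusted) and mate-pair outer-distances
    (empirical insert-size distribution, mean-shifted across deletion
    flanks). A grid of duration-targeted deletion states lets a
    first-order chain carry deletion-size memory. Includes theoretical
    power calculators for depth-only and mate-pair detection, a diploid
    read-pair simulator with planted CNVs, and an evaluation harness
    based on reciprocal-overlap matching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
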