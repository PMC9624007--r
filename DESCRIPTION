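Package: readscreen
Title: Sketching and Sampling Screens for Long-Read Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds compact "screens" of reference genomes using five k-mer
    selection strategies (uniform sampling, MinHash, weighted MinHash, order
    MinHash, and windowed minimizers), with per-genome sketch sizes chosen
    from the read length, expected per-base error rate and a target number of
    shared hashes per read. Long reads are classified to their most similar
    screen element by shared canonical k-mer hashes, either against the flat
    screen or by greedy descent through a hierarchically clustered sketch
    tree with optional downsampling. Includes host/contaminant grouping, a
    community and long-read simulator with ground truth for end-to-end
    evaluation, plain-text screen serialization, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
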