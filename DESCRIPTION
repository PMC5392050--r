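Package: phycodive
Title: Photobiont Diversity Profiling from Multiplexed Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for uncovering green-microalgal
    (photobiont) diversity from multiplexed ITS1-5.8S amplicon reads of
    lichen thalli. Covers 454-style read simulation with homopolymer
    error structure, MID demultiplexing and fixed-end trimming,
    single-linkage OTU clustering under score- and length-coverage
    thresholds, majority-rule consensus building, best-match taxonomic
    assignment against a local annotated reference set, barcode-gap
    species delimitation, statistical-parsimony haplotype networks, and
    alpha-diversity reporting (Margalef, Shannon, reciprocal Simpson,
    Pielou evenness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    vegan,
    igraph,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
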