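Package: consMSA
Title: Consistency-Based Maximum Expected Accuracy Multiple Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Progressive multiple sequence alignment by maximum expected
    accuracy. Pairwise posterior probability matrices are computed from a
    five-state pair hidden Markov model and from partition-function
    (Boltzmann-weighted) alignment ensembles, combined as root mean squares,
    compressed to a sparse row representation, and relaxed through third
    sequences by a weighted consistency transformation that never introduces
    new matrix elements. A UPGMA guide tree with ClustalW sequence weights
    drives weighted profile-profile alignment, followed by iterative
    refinement by random horizontal splits. Includes sum-of-pairs and
    total-column scoring against reference alignments and a seeded synthetic
    protein-family generator with recorded true alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
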