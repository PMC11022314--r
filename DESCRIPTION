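Package: taxonn
Title: Neural-Network Taxonomic Classification of Long Reads from
    Canonical K-mer Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free taxonomic classification of error-prone long
    reads (e.g. Oxford Nanopore) with a three-layer feed-forward neural
    network over canonical short-k-mer frequency profiles. Provides the
    full workflow: canonical k-mer feature spaces and strand-symmetric
    profiling of sequences, construction of training sets by coverage-based
    subsequence sampling from reference genomes, a synthetic-taxonomy
    generator with controlled within-genus divergence, an ONT-like
    sequencing-error simulator calibrated to a target median accuracy,
    network training with dropout and early stopping, chunked
    majority-vote classification of long reads with a confidence cutoff,
    and read-level and community-level (pseudo-mock) evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
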