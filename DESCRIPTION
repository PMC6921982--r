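Package: umidedup
Title: Error-Tolerant Collapsing of Unique Molecular Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Collapses sequencing reads that carry the same unique molecular
    identifier (UMI) up to a bounded number of substitution errors.  UMIs are
    bit-packed with a pairwise-equidistant 3-bit nucleotide code so Hamming
    distances reduce to XOR and popcount on machine words.  Duplicate
    grouping (connected components, adjacency, and directional algorithms)
    is expressed over a dynamic near-neighbor interface with eight
    interchangeable index backends, including tries, BK-trees, n-gram
    inverted indexes, Fenwick trees over BK-trees, and a hybrid of n-gram
    bins and BK-trees.  Includes a synthetic UMI dataset simulator and
    drivers for FASTQ and coordinate-keyed SAM/BAM deduplication.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
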