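Package: sgasm
Title: String Graph Assembly of DNA Reads via Suffix-Prefix Match
    Enumeration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An overlap-layout assembler for error-free DNA reads built
    around exact suffix-prefix matches (SPMs). Computes a suffix- and
    prefix-free read set over reads and their reverse complements,
    enumerates all non-redundant irreducible SPMs of length at least a
    minimum overlap by bucketed sorting of SPM-relevant suffixes (integer
    k-mer codes, counting/insertion phases with buffered merges and
    memory-bounded partitioning) and bottom-up traversal of per-bucket
    lcp-interval trees with left-context based recognition of transitive
    matches and internally contained reads, builds the assembly string
    graph (two vertices per read, two complementary edges per irreducible
    SPM), and outputs contigs along maximal unbranched walks. Includes a
    seeded read simulator, brute-force verification oracles, and a
    command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
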