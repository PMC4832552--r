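Package: bftrie
Title: Bloom Filter Trie Index for Colored k-mer Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An exact, incremental, alignment-free index for pan-genomes
    represented as colored de Bruijn graphs. Fixed-length k-mers annotated
    with per-genome color sets are stored in a burst trie whose vertices
    combine small Bloom filters with succinct prefix/suffix/cluster arrays.
    Supports k-mer lookup and insertion, lossless color-set compression,
    binary index serialization, implicit-edge graph traversal (successors,
    predecessors, branching vertices), FASTA/FASTQ ingestion with a
    minimum-occurrence filter, batch querying, and a synthetic pan-genome
    simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
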