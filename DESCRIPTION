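Package: bitonica
Title: Bitonic-Network Sorting and Chunked Alignment Engines for
    High-Throughput Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parallel pre-processing engines for high-throughput sequencing
    data, executed on an explicit simulated-distributed runtime so every
    algorithm is testable at desk scale. Implements the bitonic sorting
    network (bitonic sequences, the min/max split, bitonic merge, full
    comparator-network construction), the block-level parallel bitonic sort
    with compare-split over message-isolated workers, the Bruck all-to-all
    personalized exchange, a distributed SAM coordinate sorter that routes
    five-value records (coordinate, origin rank/offset, destination
    rank/offset) through two Bruck shuffle phases and writes contiguous
    blocks chromosome by chromosome, and an equal-nucleotide FASTQ chunker
    with deterministic parallel SAM emission behind a pluggable aligner
    contract. A fixtures module generates all test inputs; no external
    dataset is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
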