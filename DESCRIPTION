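Package: quantapa
Title: Alternative Polyadenylation Analysis from 3' End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies poly(A)-site (PAS) usage from QuantSeq-style 3' end
    sequencing alignments and tests for differential 3'UTR isoform usage
    between conditions. Reads whose last aligned position matches an
    annotated PAS within a tolerance are counted as PAS-supporting (PASS)
    reads, normalized to reads per million, and the two most-used PASs per
    gene are compared with the relative expression difference (RED)
    statistic; significance comes from a Fisher exact test or a
    beta-binomial likelihood-ratio test across replicates. Includes ddCt
    qPCR isoform-ratio arithmetic for orthogonal validation and a
    ground-truth simulator of 3' end reads (FASTQ/SAM) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    ShortRead
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
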