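Package: pairdimer
Title: Paired-Motif Orientation and Microsatellite Adjacency Analysis for
    Forkhead Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting composite transcription-factor recognition
    sites of the kind bound by FoxP3: enrichment analysis of degenerate-oligo
    pull-down sequencing libraries with 2N-motif discovery, shift-aware
    orientation analysis of motif pairs (head-to-head, head-to-tail,
    tail-to-head, tail-to-tail) with baseline-probability normalization,
    genomic paired-motif and gap-size enrichment statistics against background
    peak sets, tandem-repeat (TnG microsatellite) detection by position weight
    matrix scanning with exact p-values, repeat/dimer-site adjacency geometry,
    coverage AUC comparisons, gene-proximity profiles against differential
    expression tables, and a fully deterministic synthetic-data generator that
    produces every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
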