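Package: nanosmallrna
Title: Small RNA Processing Analysis for a Minimal Archaeal Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for small-RNA-seq data from a minimal archaeal
    genome. Detects CRISPR repeat-spacer arrays de novo and profiles crRNA
    maturation (Cas6 5' tag, 3' exonucleolytic trimming, leader identity,
    transcription start and box A promoter element); pairs trans-spliced tRNA
    half genes via reverse-complement GC-rich clamp sequences and verifies
    leaderless tRNA transcription starts; discovers C/D box and H/ACA box
    small RNAs with permuted/circular arrangement calls, genomic-context
    classification and simplified guide-target prediction. Includes a
    synthetic-data generator that plants all feature classes under a known
    processing model, a lightweight seed-and-extend micro-mapper for small
    genomes, and strand-aware coverage and read-termini calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
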