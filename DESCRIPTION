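Package: gqpep
Title: G-Quadruplex Calling and Proximal Enhancer-Promoter Pair Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying G-quadruplex (GQ) forming sequences in gene
    regulation. Provides a canonical (G3-5 N1-7)4 motif scanner and a
    pluggable window-scoring genome caller with center-context tiling,
    construction of fixed-width labeled training windows from leveled GQ
    call sets (confidence levels 1-6) with stratified negative sampling and
    fold assignment, strand-aware promoter and genomic-region annotation,
    proximal enhancer-promoter (pEP) pair construction from cCRE tracks
    with GQ flagging, enrichment statistics (observed versus expected
    shares, Fisher exact tests, interval permutation tests), single-cell
    multiome ATAC-RNA feature-linkage analysis with discordant-enhancer
    detection, and normal-versus-cancer comparison of GQ pEP landscapes.
    A seeded synthetic-data generator produces genomes with planted motifs,
    transcript annotation, cCREs, leveled call sets and linkage tables with
    known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
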