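Package: epilandscape
Title: Windowed DNA Methylation and H3K9me2 Chromatin Landscape Analysis
Version: 0.1.0
Authors@R: person("Epilandscape", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Window-based analysis of whole-genome bisulfite sequencing and
    H3K9me2 ChIP-seq data for large repeat-rich plant genomes. Tiles a genome
    into 100 bp windows carrying weighted CG/CHG/CHH methylation levels and
    ChIP read sums, builds element-anchored metaprofiles (scaled transposon
    profiles and absolute-distance TSS/TTS profiles), summarises chromatin of
    transposable-element sub-families and their flanks, catalogs large
    intronic transposon insertions, classifies transcription start sites by
    CHG methylation and H3K9me2 enrichment, and cross-tabulates gene classes
    against expression quantiles. Ships a fully parameterised synthetic
    genome/methylome/ChIP/expression simulator whose planted parameters act
    as ground truth for the analysis stack.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
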