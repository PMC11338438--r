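Package: txmeta
Title: Isoform-Resolved Liftover and Metatranscript Annotation of
    Transcript-Mapped RNA Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating, annotating and visualising RNA features
    (such as m6A modification sites) that are mapped in transcript
    coordinates. Features supplied as BED3+ records on a reference
    transcriptome are lifted to genomic coordinates through the exon chains
    of a GTF2 gene annotation, annotated with isoform-specific
    metatranscript coordinates (5'UTR scaled to [0,1), ORF to [1,2), 3'UTR
    to [2,3)) and absolute distances to start/stop codons and the nearest
    splice junctions, and summarised as binned proportion-positive
    metatranscript, metajunction and metacodon profiles with LOESS trend
    lines and 95% confidence bands. A seeded synthetic transcriptome and
    site generator with an independent brute-force truth table supports
    fully reproducible testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ggplot2,
    grid,
    optparse
Suggests:
    testthat (>= 3.0.0),
    patchwork,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'bed.R'
    'coordinates.R'
    'liftover.R'
    'annotate.R'
    'gtf.R'
    'simulate.R'
    'metaprofile.R'
    'plots.R'
    'cli.R'
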