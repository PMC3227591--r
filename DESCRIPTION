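Package: fusionfindR
Title: Discovery of Gene Fusion Transcripts from RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects chimeric (gene fusion) transcripts in single-end and
    paired-end RNA-Seq data. Builds splice-junction and pairwise fusion-junction
    sequence libraries from a reference genome and gene annotation, matches
    partially aligning single-end reads into gene fusion candidate reads (GFCRs),
    nominates candidates from discordant uniquely mapped read pairs scored with
    the paired-end fusion score (PEFS), confirms candidates with
    junction-spanning reads including alternate isoforms, calls the reading
    frame of the predicted fusion, and profiles exon-level RPKM fold changes
    that delineate expression discordance at the fusion breakpoint. Includes a
    deterministic seeded simulator of toy genomes, fusion transcripts and
    error-bearing reads for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    BiocGenerics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'align.R'
    'annotation.R'
    'expression.R'
    'fusionfindR-package.R'
    'pe_fusion.R'
    'se_fusion.R'
    'pipeline.R'
    'simulate.R'
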