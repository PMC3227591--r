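#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList elementNROWS metadata metadata<-
#' @importFrom IRanges IRanges start end width reduce narrow
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Gene model: the exon/CDS structure of one transcript
#'
#' A \code{GeneModel} describes a single transcript of a gene: its chromosome,
#' strand, exons and (optionally) the genomic span of its coding region.
#' Exons are stored in \emph{transcript order} (5' to 3' along the mRNA), so
#' for minus-strand genes exon 1 is the rightmost genomic exon.  All
#' coordinates are 1-based closed genomic coordinates.
#'
#' @slot geneId gene symbol/identifier; several transcripts may share one.
#' @slot txId transcript identifier (unique within an annotation).
#' @slot chrom chromosome name, resolvable in the genome FASTA.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons \code{IRanges} of exon genomic coordinates in transcript order.
#' @slot cds \code{IRanges} of length 0 (non-coding) or 1: the genomic span
#'   from the first to the last coding base.
#'
#' @export
setClass("GeneModel",
  representation(
    geneId = "character",
    txId = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cds = "IRanges"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) < 1L)
    msg <- c(msg, "at least one exon is required")
  if (any(width(ex) < 1L))
    msg <- c(msg, "every exon must have width >= 1")
  if (length(ex) > 1L) {
    if (length(reduce(ex, min.gapwidth = 0L)) != length(ex))
      msg <- c(msg, "exons must be non-overlapping")
    d <- diff(start(ex))
    ok <- if (object@strand == "+") all(d > 0) else all(d < 0)
    if (!ok)
      msg <- c(msg, "exons must be stored in transcript (5'->3') order")
  }
  if (length(object@cds) == 1L) {
    cs <- start(object@cds); ce <- end(object@cds)
    inExon <- function(p) any(p >= start(ex) & p <= end(ex))
    if (!inExon(cs) || !inExon(ce))
      msg <- c(msg, "cds endpoints must lie within exons")
  }
  if (length(msg)) msg else TRUE
})

#' List of gene models
#'
#' A \code{SimpleList} whose elements are \code{\linkS4class{GeneModel}}
#' objects, named by transcript id.
#'
#' @export
setClass("GeneModelList",
  contains = "SimpleList",
  prototype = prototype(elementType = "GeneModel")
)

#' Construct a GeneModel
#'
#' @param geneId,txId gene and transcript identifiers (txId defaults to geneId).
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons \code{IRanges} (or 2-column matrix of start/end) of exon
#'   genomic coordinates.  May be given in genomic order; they are re-ordered
#'   into transcript order according to \code{strand}.
#' @param cds optional length-2 numeric \code{c(start, end)} genomic span of
#'   the coding region, or \code{NULL}.
#' @return A \code{\linkS4class{GeneModel}}.
#' @examples
#' gm <- geneModel("TP53X", "chr1", "+", IRanges::IRanges(c(1, 101), c(50, 160)))
#' nExons(gm)
#' @export
geneModel <- function(geneId, chrom, strand, exons, cds = NULL, txId = geneId) {
  if (is.matrix(exons))
    exons <- IRanges(exons[, 1], exons[, 2])
  o <- order(start(exons), decreasing = (strand == "-"))
  exons <- exons[o]
  cdsIR <- if (is.null(cds)) IRanges() else IRanges(min(cds), max(cds))
  new("GeneModel", geneId = as.character(geneId), txId = as.character(txId),
      chrom = as.character(chrom), strand = strand, exons = exons, cds = cdsIR)
}

#' Construct a GeneModelList
#' @param ... \code{GeneModel} objects, or a single list of them.
#' @return A \code{\linkS4class{GeneModelList}} named by transcript id.
#' @export
GeneModelList <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is(args[[1]], "GeneModel"))
    args <- args[[1]]
  names(args) <- vapply(args, function(g) g@txId, character(1))
  new("GeneModelList", S4Vectors::SimpleList(args))
}

setMethod("show", "GeneModel", function(object) {
  cdsTxt <- if (length(object@cds))
    sprintf("CDS %d-%d", start(object@cds), end(object@cds)) else "non-coding"
  cat(sprintf("GeneModel %s (tx %s): %s%s, %d exon(s), %d bp mRNA, %s\n",
              object@geneId, object@txId, object@chrom, object@strand,
              length(object@exons), sum(width(object@exons)), cdsTxt))
})

#' Splice/fusion junction sequence library
#'
#' Holds the junction sequences produced by the x-5 rule: for read length
#' \code{x}, each junction joins up to \code{x - 5} bases from the 3' end of
#' the left (upstream) exon with up to \code{x - 5} bases from the 5' start of
#' the right (downstream) exon, both in transcript orientation.  Any read of
#' length \code{x} fully contained in such a sequence overlaps each exon by at
#' least 5 bases.
#'
#' @slot info \code{DataFrame} with one row per junction: \code{leftGene},
#'   \code{leftExon}, \code{rightGene}, \code{rightExon}, \code{leftArm},
#'   \code{rightArm}.
#' @slot sequences \code{DNAStringSet} of junction sequences, named
#'   \code{"geneL|exonL|geneR|exonR|x"}.
#' @slot readLength the read length x the library was built for.
#' @export
setClass("JunctionLibrary",
  representation(
    info = "DataFrame",
    sequences = "DNAStringSet",
    readLength = "integer"
  )
)

setValidity("JunctionLibrary", function(object) {
  msg <- character()
  if (nrow(object@info) != length(object@sequences))
    msg <- c(msg, "info rows and sequences differ in length")
  if (length(object@sequences)) {
    armSum <- object@info$leftArm + object@info$rightArm
    if (!all(width(object@sequences) == armSum))
      msg <- c(msg, "junction sequence lengths must equal leftArm + rightArm")
    x <- object@readLength
    if (any(object@info$leftArm > x - 5L) || any(object@info$rightArm > x - 5L))
      msg <- c(msg, "junction arms may not exceed x - 5")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "JunctionLibrary", function(object) {
  cat(sprintf("JunctionLibrary: %d junction(s), read length x = %d\n",
              length(object@sequences), object@readLength))
  if (length(object@sequences))
    cat(sprintf("  arm lengths %d-%d bp; sequence lengths %d-%d bp\n",
                min(c(object@info$leftArm, object@info$rightArm)),
                max(c(object@info$leftArm, object@info$rightArm)),
                min(width(object@sequences)), max(width(object@sequences))))
})

#' Pipeline configuration
#'
#' All tunable thresholds of the fusion-discovery pipeline in one validated
#' object.  Defaults are the published rule constants: partial alignments must
#' cover 20-70 percent of the read and end within 5 bp of an exon boundary,
#' reads partially hitting more than 5 genes are discarded, a single-end
#' candidate needs at least 3 unique GFCRs, intrachromosomal pairs must map at
#' least 1 Mb apart, and a paired-end candidate is prioritized when it has at
#' least 3 flanking pairs and PEFS >= 5 under the scheme +2 per pair, -1 per
#' duplicate read, -0.5 per mismatch.
#'
#' @slot readLength read length x in bp (junction libraries, simulators).
#' @slot boundaryTol bp tolerance to an exon boundary (default 5).
#' @slot partialMinFrac,partialMaxFrac allowed aligned fraction of a partial
#'   hit (defaults 0.20 and 0.70).
#' @slot maxPartialGenes discard reads partially hitting more genes (5).
#' @slot minUniqueGFCR unique GFCRs required for an SE candidate (3).
#' @slot minIntraDistance minimum intrachromosomal mate separation in bp (1e6).
#' @slot minSupportPairs flanking pairs required for prioritization (3).
#' @slot minPEFS minimum PEFS for prioritization (5).
#' @slot pairReward,duplicatePenalty,mismatchPenalty PEFS weights (2, 1, 0.5).
#' @slot rpkmPseudocount pseudocount added to RPKM fold-change ratios (0.1).
#' @slot maxMismatches end-to-end aligner mismatch budget (2).
#' @slot minLocalScore minimum local-alignment block score (16).
#' @slot exactMinLen minimum fragment length for exact short matching (8).
#' @slot gapTolerance allowed uncovered bases between GFCR parts (0).
#' @slot mapqFloor minimum MAPQ treated as unique on SAM/BAM import (1).
#' @slot mismatchSource which alignment's mismatches feed PEFS:
#'   \code{"genomic"} (default) or \code{"transcript"}.
#' @export
setClass("PipelineConfig",
  representation(
    readLength = "integer",
    boundaryTol = "integer",
    partialMinFrac = "numeric",
    partialMaxFrac = "numeric",
    maxPartialGenes = "integer",
    minUniqueGFCR = "integer",
    minIntraDistance = "numeric",
    minSupportPairs = "integer",
    minPEFS = "numeric",
    pairReward = "numeric",
    duplicatePenalty = "numeric",
    mismatchPenalty = "numeric",
    rpkmPseudocount = "numeric",
    maxMismatches = "integer",
    minLocalScore = "numeric",
    exactMinLen = "integer",
    gapTolerance = "integer",
    mapqFloor = "integer",
    mismatchSource = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!(object@partialMinFrac > 0 && object@partialMinFrac < object@partialMaxFrac &&
        object@partialMaxFrac < 1))
    msg <- c(msg, "need 0 < partialMinFrac < partialMaxFrac < 1")
  counts <- c(object@maxPartialGenes, object@minUniqueGFCR,
              object@minSupportPairs, object@exactMinLen)
  if (any(counts < 1L))
    msg <- c(msg, "count thresholds must be >= 1")
  if (any(c(object@pairReward, object@duplicatePenalty, object@mismatchPenalty) < 0))
    msg <- c(msg, "PEFS weights must be >= 0")
  if (object@readLength < 10L)
    msg <- c(msg, "readLength must be >= 10 (so that x - 5 >= 5)")
  if (!object@mismatchSource %in% c("genomic", "transcript"))
    msg <- c(msg, "mismatchSource must be 'genomic' or 'transcript'")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param readLength read length x (bp).
#' @param boundaryTol,partialMinFrac,partialMaxFrac,maxPartialGenes,minUniqueGFCR
#'   single-end filter thresholds; see \code{\linkS4class{PipelineConfig}}.
#' @param minIntraDistance,minSupportPairs,minPEFS paired-end thresholds.
#' @param pairReward,duplicatePenalty,mismatchPenalty PEFS weights.
#' @param rpkmPseudocount,maxMismatches,minLocalScore,exactMinLen,gapTolerance,mapqFloor,mismatchSource
#'   remaining knobs; see the class documentation.
#' @return A validated \code{\linkS4class{PipelineConfig}}.
#' @examples
#' cfg <- fusionConfig(readLength = 50)
#' cfg
#' @export
fusionConfig <- function(readLength = 50L, boundaryTol = 5L,
                         partialMinFrac = 0.20, partialMaxFrac = 0.70,
                         maxPartialGenes = 5L, minUniqueGFCR = 3L,
                         minIntraDistance = 1e6, minSupportPairs = 3L,
                         minPEFS = 5.0, pairReward = 2.0,
                         duplicatePenalty = 1.0, mismatchPenalty = 0.5,
                         rpkmPseudocount = 0.1, maxMismatches = 2L,
                         minLocalScore = 16, exactMinLen = 8L,
                         gapTolerance = 0L, mapqFloor = 1L,
                         mismatchSource = "genomic") {
  new("PipelineConfig",
      readLength = as.integer(readLength), boundaryTol = as.integer(boundaryTol),
      partialMinFrac = partialMinFrac, partialMaxFrac = partialMaxFrac,
      maxPartialGenes = as.integer(maxPartialGenes),
      minUniqueGFCR = as.integer(minUniqueGFCR),
      minIntraDistance = minIntraDistance,
      minSupportPairs = as.integer(minSupportPairs), minPEFS = minPEFS,
      pairReward = pairReward, duplicatePenalty = duplicatePenalty,
      mismatchPenalty = mismatchPenalty, rpkmPseudocount = rpkmPseudocount,
      maxMismatches = as.integer(maxMismatches), minLocalScore = minLocalScore,
      exactMinLen = as.integer(exactMinLen), gapTolerance = as.integer(gapTolerance),
      mapqFloor = as.integer(mapqFloor), mismatchSource = mismatchSource)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  read length x: %d bp; boundary tolerance: %d bp\n",
              object@readLength, object@boundaryTol))
  cat(sprintf("  SE: partial fraction %.2f-%.2f, <= %d genes, >= %d unique GFCRs\n",
              object@partialMinFrac, object@partialMaxFrac,
              object@maxPartialGenes, object@minUniqueGFCR))
  cat(sprintf("  PE: intra distance >= %g bp, >= %d pairs, PEFS >= %g\n",
              object@minIntraDistance, object@minSupportPairs, object@minPEFS))
  cat(sprintf("  PEFS weights: +%g/pair, -%g/duplicate, -%g/mismatch\n",
              object@pairReward, object@duplicatePenalty, object@mismatchPenalty))
})

#' A nominated gene-fusion candidate
#'
#' One candidate gene pair with its supporting evidence: the discordant read
#' pairs that flank the putative junction, the PEFS score computed from them,
#' any junction-spanning reads (with the exon pair each read supports), the
#' predicted junction and alternate isoforms, and the reading-frame call.
#'
#' @slot gene5,gene3 ids of the 5' and 3' fusion partners.
#' @slot supportPairs \code{DataFrame}, one row per supporting pair:
#'   \code{pairId}, mate placements (\code{chrom1,start1,strand1,mm1,...2}),
#'   \code{category}, and per-mate duplicate flags \code{dup1,dup2}.
#' @slot pefs the paired-end fusion score.
#' @slot spanningReads \code{DataFrame}: \code{readId}, \code{exon5},
#'   \code{exon3}, \code{mismatches}, \code{strand}.
#' @slot predictedJunction integer(2): exon ordinals (5' exon, 3' exon) of the
#'   junction with the most spanning reads; NA before confirmation.
#' @slot isoforms \code{DataFrame} of all junctions with >= 1 spanning read.
#' @slot inFrame \code{"Y"}, \code{"N"}, \code{"UTR-truncation"},
#'   \code{"unknown"}, or NA when not yet assessed.
#' @slot seSupport optional count of single-end GFCRs supporting the pair.
#' @export
setClass("FusionCandidate",
  representation(
    gene5 = "character",
    gene3 = "character",
    supportPairs = "DataFrame",
    pefs = "numeric",
    spanningReads = "DataFrame",
    predictedJunction = "integer",
    isoforms = "DataFrame",
    inFrame = "character",
    seSupport = "integer"
  ),
  prototype(
    spanningReads = S4Vectors::DataFrame(readId = character(),
                                         exon5 = integer(), exon3 = integer(),
                                         mismatches = integer(),
                                         strand = character()),
    predictedJunction = c(NA_integer_, NA_integer_),
    isoforms = S4Vectors::DataFrame(exon5 = integer(), exon3 = integer(),
                                    nReads = integer()),
    inFrame = NA_character_,
    seSupport = NA_integer_
  )
)

setValidity("FusionCandidate", function(object) {
  msg <- character()
  if (identical(object@gene5, object@gene3))
    msg <- c(msg, "gene5 and gene3 must differ")
  if (nrow(object@supportPairs) < 1L)
    msg <- c(msg, "a candidate requires at least one supporting pair (P >= 1)")
  need <- c("pairId", "chrom1", "start1", "strand1", "mm1",
            "chrom2", "start2", "strand2", "mm2", "dup1", "dup2")
  if (!all(need %in% colnames(object@supportPairs)))
    msg <- c(msg, "supportPairs lacks required columns")
  else {
    D <- sum(object@supportPairs$dup1) + sum(object@supportPairs$dup2)
    if (D > 2L * nrow(object@supportPairs))
      msg <- c(msg, "duplicate reads cannot exceed total supporting reads")
  }
  if (length(object@predictedJunction) != 2L)
    msg <- c(msg, "predictedJunction must have length 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FusionCandidate", function(object) {
  pj <- if (anyNA(object@predictedJunction)) "unconfirmed"
        else sprintf("exon %d -> exon %d", object@predictedJunction[1],
                     object@predictedJunction[2])
  cat(sprintf("FusionCandidate %s -> %s\n", object@gene5, object@gene3))
  cat(sprintf("  P = %d pair(s), D = %d duplicate read(s), M = %d mismatch(es), PEFS = %.1f\n",
              supportCount(object), duplicateCount(object),
              mismatchCount(object), object@pefs))
  cat(sprintf("  spanning reads: %d; predicted junction: %s; in-frame: %s\n",
              nrow(object@spanningReads), pj,
              ifelse(is.na(object@inFrame), "not assessed", object@inFrame)))
})

## iterate GeneModelList (an S4 SimpleList) safely in base loops
.asModelList <- function(genes) {
  if (is(genes, "SimpleList")) as.list(genes) else genes
}
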