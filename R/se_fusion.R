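#' @include AllClasses.R annotation.R align.R
NULL

## canonical (transcript-sense) coordinates of a local-alignment block: for a
## minus-strand hit the read is flipped so that the hit reads 5'->3' along the
## transcript
.canonicalBlock <- function(readStart, readEnd, strand, readLen) {
  if (strand == "+") c(readStart, readEnd)
  else c(readLen - readEnd + 1L, readLen - readStart + 1L)
}

#' Find group A: boundary-proximal partial alignments of unmapped reads
#'
#' Realigns reads that failed genomic and splice-junction alignment locally
#' against transcript sequences and retains partial hits that (i) cover
#' between \code{partialMinFrac} and \code{partialMaxFrac} of the read,
#' (ii) touch one end of the read (so a remainder exists), (iii) end within
#' \code{boundaryTol} bp of an exon boundary on the junction side, and
#' (iv) belong to reads partially hitting at most \code{maxPartialGenes}
#' distinct genes (more ambiguous reads are discarded wholesale).
#'
#' @param unmappedReads named \code{DNAStringSet} of reads that previously
#'   failed genome and splice-junction full alignment.
#' @param genes a \code{\linkS4class{GeneModelList}}.
#' @param genome named \code{DNAStringSet}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return \code{DataFrame} of partial hits: \code{readId}, \code{txId},
#'   \code{geneId}, \code{alignedFrac}, \code{boundaryDist}, canonical block
#'   interval (\code{blockStart}, \code{blockEnd}), \code{side}
#'   (\code{"prefix"}/\code{"suffix"} of the canonical read), \code{strand},
#'   transcript interval, \code{nGenesHit}, \code{readLen}.
#' @export
findGroupA <- function(unmappedReads, genes, genome, config = fusionConfig()) {
  empty <- DataFrame(readId = character(), txId = character(),
                     geneId = character(), alignedFrac = numeric(),
                     boundaryDist = integer(), blockStart = integer(),
                     blockEnd = integer(), side = character(),
                     strand = character(), txStart = integer(),
                     txEnd = integer(), nGenesHit = integer(),
                     readLen = integer())
  if (length(unmappedReads) == 0L) return(empty)
  genes <- .asModelList(genes)
  txSeqs <- transcriptSequences(genes, genome)
  gid <- vapply(genes, geneId, character(1))
  hits <- localAlign(unmappedReads, txSeqs, config)
  if (nrow(hits) == 0L) return(empty)
  readLen <- width(unmappedReads)[match(hits$readId, names(unmappedReads))]
  frac <- (hits$readEnd - hits$readStart + 1L) / readLen
  partial <- frac >= config@partialMinFrac & frac <= config@partialMaxFrac
  ## ambiguity count: distinct genes with a qualifying-fraction partial hit
  nGenes <- tapply(gid[match(hits$targetId, names(gid))][partial],
                   hits$readId[partial],
                   function(g) length(unique(g)))
  rows <- list()
  for (k in which(partial)) {
    rid <- hits$readId[k]
    ng <- as.integer(nGenes[[rid]])
    if (ng > config@maxPartialGenes) next   # ambiguous read discarded
    L <- readLen[k]
    blk <- .canonicalBlock(hits$readStart[k], hits$readEnd[k], hits$strand[k], L)
    side <- if (blk[1] == 1L) "prefix" else if (blk[2] == L) "suffix" else NA
    if (is.na(side)) next                   # interior block: no clean remainder
    tx <- genes[[hits$targetId[k]]]
    junctionTxPos <- if (side == "prefix") hits$targetEnd[k] else hits$targetStart[k]
    bd <- distanceToExonBoundary(junctionTxPos, tx)
    if (bd > config@boundaryTol) next
    rows[[length(rows) + 1L]] <- DataFrame(
      readId = rid, txId = hits$targetId[k],
      geneId = gid[[hits$targetId[k]]], alignedFrac = frac[k],
      boundaryDist = bd, blockStart = blk[1], blockEnd = blk[2],
      side = side, strand = hits$strand[k],
      txStart = hits$targetStart[k], txEnd = hits$targetEnd[k],
      nGenesHit = ng, readLen = L)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

## the canonical remainder sequence of one group-A hit
.remainderSeq <- function(read, hit) {
  canon <- if (hit$strand == "+") read else reverseComplement(read)
  if (hit$side == "prefix") subseq(canon, hit$blockEnd + 1L, length(canon))
  else subseq(canon, 1L, hit$blockStart - 1L)
}

#' Find group B: exact exon-end placements of the unaligned remainders
#'
#' Extracts the unaligned remainder of every group-A hit and matches it
#' exactly (full length) against the exon sequences of all genes, keeping
#' placements that localize within \code{boundaryTol} bp of an exon's 5' or
#' 3' end.  Remainders shorter than the exact-match floor drop out.
#'
#' @param groupA the \code{DataFrame} from \code{\link{findGroupA}}.
#' @param unmappedReads the reads the hits refer to.
#' @param genes a \code{\linkS4class{GeneModelList}}.
#' @param genome named \code{DNAStringSet}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return \code{DataFrame}: \code{readId}, \code{aRow} (row index into
#'   \code{groupA}), \code{geneId}, \code{txId}, \code{exonIndex},
#'   \code{startInExon}, \code{endInExon}, \code{exonLen}, \code{nLoci}
#'   (all exact placements of the remainder, for repeat flagging).
#' @export
findGroupB <- function(groupA, unmappedReads, genes, genome,
                       config = fusionConfig()) {
  empty <- DataFrame(readId = character(), aRow = integer(),
                     geneId = character(), txId = character(),
                     exonIndex = integer(), startInExon = integer(),
                     endInExon = integer(), exonLen = integer(),
                     nLoci = integer())
  if (nrow(groupA) == 0L) return(empty)
  genes <- .asModelList(genes)
  exonSet <- DNAStringSet()
  exonMeta <- list()
  for (g in genes) {
    es <- exonSequences(g, genome)
    names(es) <- sprintf("%s|%d", txId(g), seq_along(es))
    exonSet <- c(exonSet, es)
    exonMeta[[txId(g)]] <- g
  }
  frags <- DNAStringSet()
  fragA <- integer()
  for (k in seq_len(nrow(groupA))) {
    hit <- groupA[k, ]
    rem <- .remainderSeq(unmappedReads[[hit$readId]], hit)
    if (length(rem) < config@exactMinLen) next
    frags <- c(frags, DNAStringSet(list(rem)))
    fragA <- c(fragA, k)
  }
  if (length(frags) == 0L) return(empty)
  names(frags) <- sprintf("rem%05d", seq_along(frags))
  placements <- exactShortAlign(frags, exonSet, config)
  if (nrow(placements) == 0L) return(empty)
  nLoci <- table(placements$fragId)
  ## fusion-sense continuation: the remainder must match the exon forward
  placements <- placements[placements$strand == "+", , drop = FALSE]
  if (nrow(placements) == 0L) return(empty)
  rows <- list()
  for (k in seq_len(nrow(placements))) {
    p <- placements[k, ]
    idx <- as.integer(sub("rem", "", p$fragId))
    aRow <- fragA[idx]
    parts <- strsplit(p$targetId, "|", fixed = TRUE)[[1]]
    tx <- exonMeta[[parts[1]]]
    exonIdx <- as.integer(parts[2])
    exonLen <- width(exons(tx))[exonIdx]
    nearEnd <- min(p$start - 1L, exonLen - p$end)
    if (nearEnd > config@boundaryTol) next
    rows[[length(rows) + 1L]] <- DataFrame(
      readId = groupA$readId[aRow], aRow = aRow, geneId = geneId(tx),
      txId = txId(tx), exonIndex = exonIdx, startInExon = p$start,
      endInExon = p$end, exonLen = exonLen,
      nLoci = as.integer(nLoci[[p$fragId]]))
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Combine group A and group B into gene fusion candidate reads
#'
#' A GFCR is emitted when a read's partial alignment (group A) and the exact
#' placement of its remainder (group B) hit two \emph{different} genes; the
#' two blocks then jointly account for the entire read.  A and B hitting the
#' same gene is ordinary splice evidence, not a fusion.  The 5' partner is
#' the gene matched by the canonical read prefix.
#'
#' @param groupA,groupB outputs of \code{\link{findGroupA}} and
#'   \code{\link{findGroupB}} over the same reads.
#' @return \code{DataFrame}: \code{readId}, \code{gene5}, \code{gene3},
#'   \code{junctionOffset} (position in the canonical read where the parts
#'   meet), \code{aTxStart} (the partial alignment's transcript start, the
#'   uniqueness key), \code{boundaryDist}, \code{nLoci}, \code{readLen}.
#' @export
combineToGFCR <- function(groupA, groupB) {
  empty <- DataFrame(readId = character(), gene5 = character(),
                     gene3 = character(), junctionOffset = integer(),
                     aTxStart = integer(), boundaryDist = integer(),
                     nLoci = integer(), readLen = integer())
  if (nrow(groupB) == 0L) return(empty)
  rows <- list()
  for (k in seq_len(nrow(groupB))) {
    b <- groupB[k, ]
    a <- groupA[b$aRow, ]
    if (identical(a$geneId, b$geneId)) next  # same gene: splice, not fusion
    if (a$side == "prefix") {
      g5 <- a$geneId; g3 <- b$geneId; off <- a$blockEnd
    } else {
      g5 <- b$geneId; g3 <- a$geneId; off <- a$blockStart - 1L
    }
    rows[[length(rows) + 1L]] <- DataFrame(
      readId = a$readId, gene5 = g5, gene3 = g3,
      junctionOffset = as.integer(off), aTxStart = a$txStart,
      boundaryDist = a$boundaryDist, nLoci = b$nLoci, readLen = a$readLen)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

## homolog heuristic: identical non-empty alphabetic prefix (>= 3 chars) once
## trailing digits are stripped
.sameFamily <- function(a, b) {
  pa <- sub("[0-9]+$", "", a); pb <- sub("[0-9]+$", "", b)
  nzchar(pa) && identical(pa, pb) && nchar(pa) >= 3L && !identical(a, b)
}

#' Call single-end fusion candidates from GFCR tallies
#'
#' Tallies GFCRs per ordered gene pair, collapsing duplicates (GFCRs sharing
#' the partial alignment's start coordinate count once), and reports pairs
#' with at least \code{minUniqueGFCR} unique GFCRs.  Two likely
#' false-positive patterns are annotated but never removed: remainders
#' hitting many loci (possible repeats) and partners that look like members
#' of one gene family (shared name prefix).
#'
#' @param gfcrs the \code{DataFrame} from \code{\link{combineToGFCR}}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return \code{DataFrame}, one row per candidate pair: \code{gene5},
#'   \code{gene3}, \code{nGFCR}, \code{uniqueGFCR}, \code{repeatFlag},
#'   \code{familyFlag}, \code{readIds} (comma-separated).
#' @export
callSECandidates <- function(gfcrs, config = fusionConfig()) {
  empty <- DataFrame(gene5 = character(), gene3 = character(),
                     nGFCR = integer(), uniqueGFCR = integer(),
                     repeatFlag = logical(), familyFlag = logical(),
                     readIds = character())
  if (nrow(gfcrs) == 0L) return(empty)
  key <- paste(gfcrs$gene5, gfcrs$gene3, sep = "\r")
  rows <- list()
  for (k in unique(key)) {
    g <- gfcrs[key == k, , drop = FALSE]
    nUnique <- length(unique(g$aTxStart))
    if (nUnique < config@minUniqueGFCR) next
    rows[[length(rows) + 1L]] <- DataFrame(
      gene5 = g$gene5[1], gene3 = g$gene3[1],
      nGFCR = nrow(g), uniqueGFCR = as.integer(nUnique),
      repeatFlag = stats::median(g$nLoci) > config@maxPartialGenes,
      familyFlag = .sameFamily(g$gene5[1], g$gene3[1]),
      readIds = paste(unique(g$readId), collapse = ","))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$uniqueGFCR, out$gene5, out$gene3), , drop = FALSE]
}
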