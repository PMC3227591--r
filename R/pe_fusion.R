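#' @include AllClasses.R AllGenerics.R annotation.R align.R
NULL

#' Select discordant uniquely-mapped read pairs
#'
#' Keeps pairs whose mates both mapped fully and uniquely to the reference
#' genome and whose placement suggests a rearrangement: mates on different
#' chromosomes (\code{interchromosomal}) or on the same chromosome but at
#' least \code{minIntraDistance} apart (\code{long_intrachromosomal}; the
#' 1 Mb default guards against large introns masquerading as
#' rearrangements).  Concordant pairs are excluded.
#'
#' @param pairs a pair table from \code{\link{pairAlignments}} or
#'   \code{\link{importedPairs}}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return The discordant subset with an added \code{category} column.
#' @export
selectDiscordantPairs <- function(pairs, config = fusionConfig()) {
  ok <- pairs$unique1 & pairs$unique2 & pairs$full1 & pairs$full2
  pairs <- pairs[ok, , drop = FALSE]
  inter <- pairs$chrom1 != pairs$chrom2
  dist <- abs(pairs$start1 - pairs$start2)
  longIntra <- !inter & dist >= config@minIntraDistance
  out <- pairs[inter | longIntra, , drop = FALSE]
  out$category <- ifelse(out$chrom1 != out$chrom2,
                         "interchromosomal", "long_intrachromosomal")
  out
}

#' Assign discordant pairs to candidate gene pairs
#'
#' Realigns the mate sequences of each discordant pair to transcript
#' sequences and keeps pairs whose mates land in two distinct genes.  The 5'
#' partner is inferred from transcript-alignment strand: a fragment drawn
#' from a fusion transcript yields one mate matching the 5' partner's mRNA
#' forward and one matching the 3' partner's mRNA in reverse complement.
#' When both mates align to their transcripts on the same strand the
#' orientation is ambiguous and both orientations are emitted.  Mates hitting
#' more than one gene ambiguously drop the pair.
#'
#' @param discordant output of \code{\link{selectDiscordantPairs}}.
#' @param reads1,reads2 named \code{DNAStringSet}s of mate sequences.
#' @param genes a \code{\linkS4class{GeneModelList}}.
#' @param genome named \code{DNAStringSet}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return \code{DataFrame}: \code{pairId}, \code{gene5}, \code{gene3},
#'   genomic mate placements (\code{chrom1}, \code{start1}, \code{strand1},
#'   \code{mm1}, and mate-2 equivalents), \code{category},
#'   \code{ambiguousOrientation}.
#' @export
assignPairsToGenes <- function(discordant, reads1, reads2, genes, genome,
                               config = fusionConfig()) {
  empty <- DataFrame(pairId = character(), gene5 = character(),
                     gene3 = character(), chrom1 = character(),
                     start1 = integer(), strand1 = character(),
                     mm1 = integer(), chrom2 = character(),
                     start2 = integer(), strand2 = character(),
                     mm2 = integer(), category = character(),
                     ambiguousOrientation = logical())
  if (nrow(discordant) == 0L) return(empty)
  genes <- .asModelList(genes)
  txSeqs <- transcriptSequences(genes, genome)
  gid <- vapply(genes, geneId, character(1))
  ids <- discordant$pairId
  a1 <- alignEndToEnd(reads1[ids], txSeqs, config)
  a2 <- alignEndToEnd(reads2[ids], txSeqs, config)
  mateGene <- function(aln, id) {
    h <- aln[aln$readId == id, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    gs <- unique(gid[match(h$targetId, names(gid))])
    if (length(gs) != 1L) return(NA)        # ambiguous across genes: drop
    list(gene = gs, strand = h$strand[1],
         mm = h$mismatches[1])
  }
  rows <- list()
  for (k in seq_len(nrow(discordant))) {
    p <- discordant[k, ]
    m1 <- mateGene(a1, p$pairId); m2 <- mateGene(a2, p$pairId)
    if (is.null(m1) || is.null(m2)) next         # failed transcript realignment
    if (identical(m1, NA) || identical(m2, NA)) next
    if (identical(m1$gene, m2$gene)) next        # both mates in one gene
    mm1 <- if (config@mismatchSource == "genomic") p$mm1 else m1$mm
    mm2 <- if (config@mismatchSource == "genomic") p$mm2 else m2$mm
    base <- DataFrame(pairId = p$pairId, gene5 = NA_character_,
                      gene3 = NA_character_, chrom1 = p$chrom1,
                      start1 = p$start1, strand1 = p$strand1,
                      mm1 = as.integer(mm1), chrom2 = p$chrom2,
                      start2 = p$start2, strand2 = p$strand2,
                      mm2 = as.integer(mm2), category = p$category,
                      ambiguousOrientation = FALSE)
    if (m1$strand != m2$strand) {
      if (m1$strand == "+") { base$gene5 <- m1$gene; base$gene3 <- m2$gene }
      else                  { base$gene5 <- m2$gene; base$gene3 <- m1$gene }
      rows[[length(rows) + 1L]] <- base
    } else {
      ## ambiguous orientation: emit both so junction search can adjudicate
      base$ambiguousOrientation <- TRUE
      fwd <- base; fwd$gene5 <- m1$gene; fwd$gene3 <- m2$gene
      rev <- base; rev$gene5 <- m2$gene; rev$gene3 <- m1$gene
      rows[[length(rows) + 1L]] <- fwd
      rows[[length(rows) + 1L]] <- rev
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' The paired-end fusion score
#'
#' \code{pefsScore} evaluates the scoring scheme directly:
#' \deqn{PEFS = 2P - D - 0.5M}
#' with +2 awarded per identified supporting read pair (P), -1 per duplicate
#' read (D; a supporting read with the same start coordinate as another
#' supporting read), and -0.5 per mismatch in a supporting read (M).
#'
#' @param P number of supporting read pairs (>= 1).
#' @param D number of duplicate supporting reads.
#' @param M total mismatches across supporting reads.
#' @param pairReward,duplicatePenalty,mismatchPenalty the scheme weights.
#' @return The numeric score (vectorized over P, D, M).
#' @examples
#' pefsScore(3, 0, 0)   # the three-pair worked example: 6
#' pefsScore(5, 0, 1)   # 9.5
#' @export
pefsScore <- function(P, D, M, pairReward = 2, duplicatePenalty = 1,
                      mismatchPenalty = 0.5) {
  if (any(P < 1)) stop("PEFS requires at least one supporting pair (P >= 1)")
  if (any(D < 0) || any(M < 0)) stop("D and M must be non-negative")
  pairReward * P - duplicatePenalty * D - mismatchPenalty * M
}

#' @describeIn computePEFS recompute the score of a candidate from its
#'   supporting evidence (P, D and M are re-derived from the support table).
#' @param config a \code{\linkS4class{PipelineConfig}} supplying the weights.
#' @export
setMethod("computePEFS", "FusionCandidate", function(x, config = fusionConfig()) {
  pefsScore(supportCount(x), duplicateCount(x), mismatchCount(x),
            config@pairReward, config@duplicatePenalty, config@mismatchPenalty)
})

#' Build scored fusion candidates from gene-assigned pairs
#'
#' Groups assigned pairs by (gene5, gene3), flags duplicate supporting reads
#' (same chromosome, strand and start coordinate as an earlier supporting
#' read of the same candidate), sums mismatches, and computes the PEFS.
#'
#' @param assigned output of \code{\link{assignPairsToGenes}}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return A list of \code{\linkS4class{FusionCandidate}} objects.
#' @export
buildCandidates <- function(assigned, config = fusionConfig()) {
  if (nrow(assigned) == 0L) return(list())
  key <- paste(assigned$gene5, assigned$gene3, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    g <- assigned[key == k, , drop = FALSE]
    key1 <- paste(g$chrom1, g$strand1, g$start1)
    key2 <- paste(g$chrom2, g$strand2, g$start2)
    allKeys <- c(rbind(key1, key2))        # interleave mate1/mate2 per pair
    dup <- duplicated(allKeys)
    dup1 <- dup[seq(1L, length(dup), by = 2L)]
    dup2 <- dup[seq(2L, length(dup), by = 2L)]
    support <- DataFrame(pairId = g$pairId, chrom1 = g$chrom1,
                         start1 = g$start1, strand1 = g$strand1, mm1 = g$mm1,
                         chrom2 = g$chrom2, start2 = g$start2,
                         strand2 = g$strand2, mm2 = g$mm2,
                         category = g$category, dup1 = dup1, dup2 = dup2)
    cand <- new("FusionCandidate", gene5 = g$gene5[1], gene3 = g$gene3[1],
                supportPairs = support, pefs = 0)
    cand@pefs <- computePEFS(cand, config)
    out[[length(out) + 1L]] <- cand
  }
  names(out) <- vapply(out, function(x) paste(x@gene5, x@gene3, sep = "->"),
                       character(1))
  out
}

#' Prioritize candidates by support and PEFS
#'
#' Retains candidates with at least \code{minSupportPairs} flanking pairs
#' \emph{and} PEFS at least \code{minPEFS}, sorted by PEFS (descending), then
#' pair count (descending), then gene pair (lexicographic tie-break).
#'
#' @param candidates list of \code{\linkS4class{FusionCandidate}}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return The filtered, ordered list.
#' @export
prioritizeCandidates <- function(candidates, config = fusionConfig()) {
  if (!length(candidates)) return(list())
  keep <- vapply(candidates, function(x)
    supportCount(x) >= config@minSupportPairs && pefs(x) >= config@minPEFS,
    logical(1))
  kept <- candidates[keep]
  if (!length(kept)) return(list())
  o <- order(-vapply(kept, pefs, numeric(1)),
             -vapply(kept, supportCount, integer(1)),
             vapply(kept, function(x) paste(x@gene5, x@gene3), character(1)))
  kept[o]
}

## all gene models carrying a given gene id
.modelsForGene <- function(genes, id) {
  genes <- .asModelList(genes)
  genes[vapply(genes, function(g) identical(geneId(g), id), logical(1))]
}

#' Search for junction-spanning reads confirming a candidate
#'
#' Aligns the still-unmapped reads against the library of \emph{all} possible
#' fusion junctions between the candidate's partners (restricting the search
#' space to the two genes).  Each uniquely placed, fully contained read votes
#' for one (5' exon, 3' exon) junction; the junction with the most votes
#' becomes the predicted junction and every junction with at least one read
#' is retained as an isoform.  Zero spanning reads leave the candidate
#' unconfirmed (predicted junction NA).
#'
#' @param candidate a \code{\linkS4class{FusionCandidate}}.
#' @param unmappedReads named \code{DNAStringSet} of reads unmapped to genome
#'   and splice junctions.
#' @param genes a \code{\linkS4class{GeneModelList}}.
#' @param genome named \code{DNAStringSet}.
#' @param config a \code{\linkS4class{PipelineConfig}}; junctions are built
#'   for \code{readLength}.
#' @return The candidate updated with \code{spanningReads},
#'   \code{predictedJunction} and \code{isoforms}.
#' @export
findSpanningReads <- function(candidate, unmappedReads, genes, genome,
                              config = fusionConfig()) {
  libs <- list()
  for (m5 in .modelsForGene(genes, candidate@gene5))
    for (m3 in .modelsForGene(genes, candidate@gene3))
      libs[[length(libs) + 1L]] <- buildFusionJunctionLibrary(
        m5, m3, genome, config@readLength)
  if (!length(libs))
    stop("candidate genes not found in the annotation")
  lib <- .combineJunctionLibraries(libs)
  spanning <- candidate@spanningReads[0, ]
  if (length(unmappedReads)) {
    seqs <- junctionSeqs(lib)
    names(seqs) <- sprintf("j%05d", seq_along(seqs))   # unique per record
    aln <- alignEndToEnd(unmappedReads, seqs, config)
    aln <- aln[aln$unique, , drop = FALSE]
    if (nrow(aln)) {
      idx <- as.integer(sub("j", "", aln$targetId))
      info <- junctionInfo(lib)
      spanning <- DataFrame(readId = aln$readId,
                            exon5 = info$leftExon[idx],
                            exon3 = info$rightExon[idx],
                            mismatches = aln$mismatches,
                            strand = aln$strand)
    }
  }
  candidate@spanningReads <- spanning
  if (nrow(spanning)) {
    tab <- as.data.frame(table(exon5 = spanning$exon5, exon3 = spanning$exon3),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    tab$exon5 <- as.integer(tab$exon5); tab$exon3 <- as.integer(tab$exon3)
    tab <- tab[order(-tab$Freq, tab$exon5, tab$exon3), , drop = FALSE]
    candidate@isoforms <- DataFrame(exon5 = tab$exon5, exon3 = tab$exon3,
                                    nReads = as.integer(tab$Freq))
    candidate@predictedJunction <- c(tab$exon5[1], tab$exon3[1])
  } else {
    candidate@isoforms <- candidate@isoforms[0, ]
    candidate@predictedJunction <- c(NA_integer_, NA_integer_)
  }
  candidate
}

## transcript coordinate of a genomic position within a gene model
.genomicToTx <- function(gene, gpos) {
  ex <- exons(gene)
  ends <- txExonEnds(gene)
  before <- c(0L, head(ends, -1L))
  for (k in seq_along(ex)) {
    if (gpos >= start(ex)[k] && gpos <= end(ex)[k]) {
      off <- if (geneStrand(gene) == "+") gpos - start(ex)[k] + 1L
             else end(ex)[k] - gpos + 1L
      return(before[k] + off)
    }
  }
  stop("genomic position ", gpos, " is not exonic in ", txId(gene))
}

## transcript coordinate of the 5'-most CDS base
.cdsTxStart <- function(gene) {
  cds <- cdsSpan(gene)
  if (!length(cds)) return(NA_integer_)
  gpos <- if (geneStrand(gene) == "+") start(cds) else end(cds)
  .genomicToTx(gene, gpos)
}

.cdsTxEnd <- function(gene) {
  cds <- cdsSpan(gene)
  if (!length(cds)) return(NA_integer_)
  gpos <- if (geneStrand(gene) == "+") end(cds) else start(cds)
  .genomicToTx(gene, gpos)
}

#' Determine whether the predicted fusion is in frame
#'
#' Compares coding phase across the predicted junction: the fusion is in
#' frame (\code{"Y"}) when the number of 5'-partner coding bases upstream of
#' the donor boundary and the number of 3'-partner coding bases upstream of
#' the acceptor boundary are congruent modulo 3, so the downstream partner's
#' codon frame is preserved.  When the donor boundary lies inside the 5'
#' partner's 5' UTR the call is \code{"UTR-truncation"}: no 5' coding
#' sequence is contributed and the product is a (possibly truncated) 3'
#' partner protein.  Missing CDS annotation yields \code{"unknown"} with a
#' warning.
#'
#' @param candidate a \code{\linkS4class{FusionCandidate}} with a predicted
#'   junction.
#' @param genes a \code{\linkS4class{GeneModelList}} with CDS spans.
#' @return The candidate with its \code{inFrame} slot set.
#' @export
determineInFrame <- function(candidate, genes) {
  pj <- candidate@predictedJunction
  if (anyNA(pj))
    stop("candidate has no predicted junction; run findSpanningReads first")
  m5 <- .modelsForGene(genes, candidate@gene5)[[1]]
  m3 <- .modelsForGene(genes, candidate@gene3)[[1]]
  cds5 <- .cdsTxStart(m5); cds3 <- .cdsTxStart(m3)
  if (is.na(cds5) || is.na(cds3)) {
    warning("missing CDS annotation for ", candidate@gene5, " or ",
            candidate@gene3, "; frame unknown")
    candidate@inFrame <- "unknown"
    return(candidate)
  }
  L5 <- txExonEnds(m5)[pj[1]]              # mRNA bases upstream of the donor
  if (L5 < cds5) {
    candidate@inFrame <- "UTR-truncation"
    return(candidate)
  }
  ends3 <- txExonEnds(m3)
  A3 <- if (pj[2] == 1L) 1L else ends3[pj[2] - 1L] + 1L  # first kept base
  cdsEnd3 <- .cdsTxEnd(m3)
  if (A3 <= cds3 || A3 > cdsEnd3) {
    ## acceptor outside the 3' partner's CDS while the donor is coding:
    ## the downstream frame is not defined by phase arithmetic
    candidate@inFrame <- "N"
    return(candidate)
  }
  phase5 <- (L5 - cds5 + 1L) %% 3L
  phase3 <- (A3 - cds3) %% 3L
  candidate@inFrame <- if (phase5 == phase3) "Y" else "N"
  candidate
}
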