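#' @include AllClasses.R annotation.R
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Count uniquely mapped reads per exon
#'
#' Counts, for each exon of a gene, the genomic alignments flagged unique
#' that overlap the exon by at least one base.  Multi-mapped reads contribute
#' nothing; a read straddling two adjacent exons counts once for each.
#'
#' @param alignments a \code{DataFrame} of genomic alignments
#'   (\code{\link{alignEndToEnd}} or \code{\link{importAlignments}}) with
#'   \code{targetId}, \code{start}, \code{end}, \code{unique}.
#' @param gene a \code{\linkS4class{GeneModel}}.
#' @return Integer vector of per-exon counts in transcript order.
#' @export
countReadsPerExon <- function(alignments, gene) {
  n <- nExons(gene)
  uniq <- alignments[alignments$unique, , drop = FALSE]
  uniq <- uniq[uniq$targetId == chrom(gene), , drop = FALSE]
  if (nrow(uniq) == 0L) return(integer(n))
  readsGR <- GRanges(uniq$targetId, IRanges(uniq$start, uniq$end))
  exonsGR <- GRanges(chrom(gene), exons(gene))
  ov <- findOverlaps(exonsGR, readsGR, minoverlap = 1L)
  counts <- tabulate(queryHits(ov), nbins = n)
  as.integer(counts)
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' \code{rpkm = count / (exonLen/1000) / (totalMapped/1e6)}; linear in the
#' count, inverse-linear in exon length and library size.
#'
#' @param count unique read count(s) for the exon(s).
#' @param exonLen exon length(s) in bp (> 0).
#' @param totalMapped total uniquely mapped reads in the sample (> 0).
#' @return Numeric RPKM value(s).
#' @export
computeRPKM <- function(count, exonLen, totalMapped) {
  if (any(exonLen <= 0)) stop("exon length must be positive")
  if (any(totalMapped <= 0)) stop("total mapped reads must be positive")
  count / (exonLen / 1e3) / (totalMapped / 1e6)
}

#' Per-exon expression profile of one gene in one sample
#'
#' @param alignments genomic alignments of the sample.
#' @param gene a \code{\linkS4class{GeneModel}}.
#' @param totalMapped library size; defaults to the number of distinct
#'   uniquely mapped reads in \code{alignments}.
#' @return \code{DataFrame}: \code{geneId}, \code{exon}, \code{count},
#'   \code{exonLen}, \code{rpkm}.
#' @export
exonExpressionProfile <- function(alignments, gene, totalMapped = NULL) {
  if (is.null(totalMapped))
    totalMapped <- length(unique(alignments$readId[alignments$unique]))
  counts <- countReadsPerExon(alignments, gene)
  lens <- width(exons(gene))
  DataFrame(geneId = geneId(gene), exon = seq_along(counts),
            count = counts, exonLen = lens,
            rpkm = computeRPKM(counts, lens, totalMapped))
}

#' Per-exon expression fold change against fusion-negative references
#'
#' For each exon, FC = RPKM in the fusion-bearing sample over the arithmetic
#' mean RPKM across the fusion-negative reference samples, stabilized with a
#' pseudocount in both numerator and denominator; the log2 transform is
#' reported alongside.  Exons whose reference mean is exactly zero while the
#' sample expresses are flagged.
#'
#' @param sampleProfile profile of the fusion-bearing sample
#'   (\code{\link{exonExpressionProfile}}).
#' @param referenceProfiles list (>= 1) of profiles of fusion-negative
#'   samples over the \emph{same} exon set.
#' @param pseudocount RPKM pseudocount added to both ratio terms.
#' @return \code{sampleProfile} with added \code{refRpkm}, \code{fc},
#'   \code{log2fc}, \code{zeroRefFlag}.
#' @export
computeFoldChange <- function(sampleProfile, referenceProfiles,
                              pseudocount = 0.1) {
  if (!length(referenceProfiles))
    stop("at least one reference profile is required")
  for (rp in referenceProfiles) {
    if (nrow(rp) != nrow(sampleProfile) ||
        !all(rp$exon == sampleProfile$exon) ||
        !all(rp$geneId == sampleProfile$geneId))
      stop("reference and sample profiles cover different exon sets")
  }
  refMat <- vapply(referenceProfiles, function(rp) rp$rpkm,
                   numeric(nrow(sampleProfile)))
  refMean <- rowMeans(matrix(refMat, nrow = nrow(sampleProfile)))
  fc <- (sampleProfile$rpkm + pseudocount) / (refMean + pseudocount)
  out <- sampleProfile
  out$refRpkm <- refMean
  out$fc <- fc
  out$log2fc <- log2(fc)
  out$zeroRefFlag <- refMean == 0 & sampleProfile$rpkm > 0
  out
}

#' Expression discordance around a fusion breakpoint
#'
#' Summarizes a per-exon log2 fold-change profile as the mean over the exons
#' upstream of the breakpoint, the mean from the breakpoint exon onward, and
#' their difference — the step that delineates breakpoint-driven expression
#' discordance.  No significance test is performed.
#'
#' @param log2fc per-exon log2 fold changes in transcript order.
#' @param breakpointExon ordinal of the first exon of the downstream block.
#' @return list \code{upstreamMean}, \code{downstreamMean},
#'   \code{difference}; means are \code{NA} (difference undefined) when a
#'   block is empty.
#' @export
breakpointDiscordance <- function(log2fc, breakpointExon) {
  n <- length(log2fc)
  if (breakpointExon < 1L || breakpointExon > n)
    stop("breakpoint exon ordinal out of range [1, ", n, "]")
  up <- if (breakpointExon > 1L) log2fc[seq_len(breakpointExon - 1L)] else numeric()
  down <- log2fc[breakpointExon:n]
  upM <- if (length(up)) mean(up) else NA_real_
  downM <- if (length(down)) mean(down) else NA_real_
  list(upstreamMean = upM, downstreamMean = downM,
       difference = if (is.na(upM) || is.na(downM)) NA_real_ else downM - upM)
}

#' Write expression profiles as TSV
#'
#' @param profile a \code{DataFrame} from \code{\link{computeFoldChange}} or
#'   \code{\link{exonExpressionProfile}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTSV <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
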