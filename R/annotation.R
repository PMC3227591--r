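#' @include AllClasses.R AllGenerics.R
#' @importFrom Biostrings subseq writeXStringSet readDNAStringSet xscat
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges shift
NULL

## ---- sequence access -------------------------------------------------------

#' Exon and transcript sequences of a gene model
#'
#' \code{exonSequences} returns each exon's sequence in transcript orientation
#' (minus-strand exons are reverse-complemented); \code{transcriptSequence}
#' concatenates them into the mRNA sequence.
#'
#' @param gene a \code{\linkS4class{GeneModel}}.
#' @param genome a named \code{DNAStringSet} of chromosome sequences.
#' @return A \code{DNAStringSet} (one element per exon) or a \code{DNAString}.
#' @export
exonSequences <- function(gene, genome) {
  chromSeq <- genome[[chrom(gene)]]
  if (is.null(chromSeq))
    stop("chromosome '", chrom(gene), "' not found in genome")
  ex <- exons(gene)
  seqs <- DNAStringSet(lapply(seq_along(ex), function(i)
    subseq(chromSeq, start(ex)[i], end(ex)[i])))
  if (geneStrand(gene) == "-")
    seqs <- reverseComplement(seqs)
  names(seqs) <- sprintf("%s|exon%d", geneId(gene), seq_along(ex))
  seqs
}

#' @rdname exonSequences
#' @export
transcriptSequence <- function(gene, genome) {
  unlist(exonSequences(gene, genome))
}

#' Transcript sequences of a gene model list
#'
#' @param genes a \code{\linkS4class{GeneModelList}}.
#' @param genome a named \code{DNAStringSet}.
#' @return A \code{DNAStringSet} named by transcript id.
#' @export
transcriptSequences <- function(genes, genome) {
  genes <- .asModelList(genes)
  out <- DNAStringSet(lapply(genes, transcriptSequence, genome = genome))
  names(out) <- vapply(genes, txId, character(1))
  out
}

## transcript-coordinate ends of each exon: exon k covers
## (cumEnds[k-1]+1) .. cumEnds[k] on the mRNA
txExonEnds <- function(gene) cumsum(width(exons(gene)))

## ---- annotation loading ----------------------------------------------------

#' Load gene annotation into gene models
#'
#' Reads GTF (exon/CDS features grouped by \code{transcript_id}) or BED12
#' (blocks as exons, thick range as CDS) and returns one
#' \code{\linkS4class{GeneModel}} per transcript, with minus-strand exon lists
#' reversed into transcript order.  Chromosome names must resolve in
#' \code{genome}; a record on an unknown chromosome is a fatal error, and a
#' transcript without exons is rejected with a warning.
#'
#' @param path annotation file (.gtf/.gff or .bed with 12 columns).
#' @param genome a named \code{DNAStringSet} used to validate chromosomes.
#' @param format \code{"auto"} (by extension), \code{"gtf"} or \code{"bed"}.
#' @return A \code{\linkS4class{GeneModelList}}.
#' @export
loadAnnotation <- function(path, genome, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff", "gff2")) "gtf"
              else if (ext == "bed") "bed"
              else stop("cannot infer annotation format from extension '", ext, "'")
  }
  models <- if (format == "gtf") .loadGTF(path) else .loadBED12(path)
  for (g in models) {
    if (!chrom(g) %in% names(genome))
      stop("annotation record '", txId(g), "' refers to chromosome '",
           chrom(g), "' absent from the genome")
  }
  GeneModelList(models)
}

.loadGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  exo <- gr[type == "exon"]
  if (length(exo) == 0L)
    stop("no exon features found in '", path, "'")
  txids <- as.character(exo$transcript_id)
  cdsGr <- gr[type == "CDS"]
  cdsTx <- as.character(cdsGr$transcript_id)
  allTx <- unique(as.character(gr$transcript_id))
  allTx <- allTx[!is.na(allTx)]
  models <- list()
  for (tx in allTx) {
    e <- exo[txids == tx]
    if (length(e) == 0L) {
      warning("transcript '", tx, "' has no exons; record rejected")
      next
    }
    gid <- as.character(e$gene_id[1])
    if (is.na(gid) || !nzchar(gid)) gid <- tx
    cds <- NULL
    cc <- cdsGr[cdsTx == tx]
    if (length(cc))
      cds <- c(min(start(cc)), max(end(cc)))
    models[[tx]] <- geneModel(
      geneId = gid, txId = tx,
      chrom = as.character(GenomicRanges::seqnames(e))[1],
      strand = as.character(BiocGenerics::strand(e))[1],
      exons = IRanges(start(e), end(e)), cds = cds)
  }
  models
}

.loadBED12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks))
    stop("'", path, "' is not BED12 (no block definitions)")
  models <- list()
  for (i in seq_along(gr)) {
    nm <- gr$name[i]
    blocks <- gr$blocks[[i]]
    ex <- IRanges::shift(blocks, start(gr)[i] - 1L)
    cds <- NULL
    if (!is.null(gr$thick)) {
      th <- gr$thick[i]
      if (width(th) > 1L || (width(th) == 1L && start(th) > start(gr)[i]))
        cds <- c(start(th), end(th))
    }
    models[[nm]] <- geneModel(
      geneId = nm, txId = nm,
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(BiocGenerics::strand(gr))[i],
      exons = ex, cds = cds)
  }
  models
}

## ---- junction libraries ----------------------------------------------------

## arms via the x-5 rule: up to x-5 bases from the 3' end of the left exon and
## the 5' start of the right exon (or the whole exon when shorter)
.junctionArm <- function(exonSeq, x, side) {
  arm <- min(x - 5L, length(exonSeq))
  if (side == "left")
    subseq(exonSeq, length(exonSeq) - arm + 1L, length(exonSeq))
  else
    subseq(exonSeq, 1L, arm)
}

.makeJunctions <- function(leftSeqs, rightSeqs, leftGene, rightGene,
                           leftIdx, rightIdx, x) {
  n <- length(leftIdx)
  seqs <- vector("list", n)
  leftArm <- rightArm <- integer(n)
  for (k in seq_len(n)) {
    la <- .junctionArm(leftSeqs[[leftIdx[k]]], x, "left")
    ra <- .junctionArm(rightSeqs[[rightIdx[k]]], x, "right")
    leftArm[k] <- length(la); rightArm[k] <- length(ra)
    seqs[[k]] <- xscat(la, ra)
  }
  seqs <- DNAStringSet(seqs)
  names(seqs) <- sprintf("%s|%d|%s|%d|%d", leftGene, leftIdx,
                         rightGene, rightIdx, x)
  info <- DataFrame(leftGene = rep(leftGene, n), leftExon = leftIdx,
                    rightGene = rep(rightGene, n), rightExon = rightIdx,
                    leftArm = leftArm, rightArm = rightArm)
  new("JunctionLibrary", info = info, sequences = seqs,
      readLength = as.integer(x))
}

#' Build the splice-junction sequence library
#'
#' For every adjacent exon pair of every gene, joins up to \code{x - 5} bases
#' from the upstream exon's 3' end with up to \code{x - 5} bases from the
#' downstream exon's 5' start (the whole exon when it is shorter).  Reads of
#' length \code{x} spanning a splice junction fail genomic alignment but map
#' fully inside these sequences, overlapping each exon by at least 5 bases.
#'
#' @param genes a \code{\linkS4class{GeneModelList}} (or list of GeneModel).
#' @param genome named \code{DNAStringSet}.
#' @param x read length in bp; must be >= 10.
#' @return A \code{\linkS4class{JunctionLibrary}}.  Single-exon genes
#'   contribute no records.
#' @examples
#' \dontrun{lib <- buildSpliceJunctionLibrary(genes, genome, x = 50)}
#' @export
buildSpliceJunctionLibrary <- function(genes, genome, x) {
  genes <- .asModelList(genes)
  x <- as.integer(x)
  if (x < 10L) stop("read length x must be >= 10 (so that x - 5 >= 5)")
  libs <- list()
  for (g in genes) {
    n <- nExons(g)
    if (n < 2L) next
    seqs <- exonSequences(g, genome)
    libs[[length(libs) + 1L]] <- .makeJunctions(
      seqs, seqs, geneId(g), geneId(g),
      seq_len(n - 1L), seq_len(n - 1L) + 1L, x)
  }
  if (!length(libs))
    return(new("JunctionLibrary",
               info = DataFrame(leftGene = character(), leftExon = integer(),
                                rightGene = character(), rightExon = integer(),
                                leftArm = integer(), rightArm = integer()),
               sequences = DNAStringSet(), readLength = x))
  .combineJunctionLibraries(libs)
}

.combineJunctionLibraries <- function(libs) {
  new("JunctionLibrary",
      info = do.call(rbind, lapply(libs, junctionInfo)),
      sequences = do.call(c, lapply(libs, junctionSeqs)),
      readLength = readLengthX(libs[[1]]))
}

#' Build the pairwise fusion-junction library for two genes
#'
#' Enumerates all possible fusion junctions between a 5' partner and a 3'
#' partner: one record for every (exon i of \code{gene5}, exon j of
#' \code{gene3}) pair, arms built by the same x-5 rule as the splice-junction
#' library.  Searching reads against this library finds junction-spanning
#' evidence for any fusion isoform, and swapping the arguments yields the
#' disjoint reciprocal-fusion library.
#'
#' @param gene5,gene3 \code{\linkS4class{GeneModel}}s of the 5' and 3'
#'   partners; must differ.
#' @param genome named \code{DNAStringSet}.
#' @param x read length in bp.
#' @return A \code{\linkS4class{JunctionLibrary}} with
#'   \code{nExons(gene5) * nExons(gene3)} records.
#' @export
buildFusionJunctionLibrary <- function(gene5, gene3, genome, x) {
  x <- as.integer(x)
  if (x < 10L) stop("read length x must be >= 10 (so that x - 5 >= 5)")
  if (identical(geneId(gene5), geneId(gene3)))
    stop("gene5 and gene3 must be different genes")
  grid <- expand.grid(i = seq_len(nExons(gene5)), j = seq_len(nExons(gene3)))
  .makeJunctions(exonSequences(gene5, genome), exonSequences(gene3, genome),
                 geneId(gene5), geneId(gene3), grid$i, grid$j, x)
}

#' Distance from a transcript position to the nearest exon boundary
#'
#' Positions are 1-based transcript-relative coordinates.  The distance is 0
#' when the position is the first or last base of an exon.
#'
#' @param position 1-based position(s) on the mRNA.
#' @param gene a \code{\linkS4class{GeneModel}}.
#' @return Non-negative integer distance(s) in bp.
#' @export
distanceToExonBoundary <- function(position, gene) {
  L <- txLength(gene)
  if (any(position < 1L | position > L))
    stop("position out of transcript range [1, ", L, "]")
  ends <- txExonEnds(gene)
  starts <- c(1L, head(ends, -1L) + 1L)
  vapply(position, function(p) {
    k <- which(p <= ends)[1]
    min(p - starts[k], ends[k] - p)
  }, integer(1))
}

#' Export a junction library as FASTA
#'
#' Headers follow the \code{geneL|exonL|geneR|exonR|x} convention.
#'
#' @param lib a \code{\linkS4class{JunctionLibrary}}.
#' @param path output FASTA file.
#' @return \code{path}, invisibly.
#' @export
writeJunctionFasta <- function(lib, path) {
  writeXStringSet(junctionSeqs(lib), path)
  invisible(path)
}

#' Export gene models as BED12
#'
#' @param genes a \code{\linkS4class{GeneModelList}}.
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationBED <- function(genes, path) {
  genes <- .asModelList(genes)
  lines <- vapply(genes, function(g) {
    ex <- exons(g)
    o <- order(start(ex))          # BED blocks in genomic order
    ex <- ex[o]
    chromStart <- min(start(ex)) - 1L
    cds <- cdsSpan(g)
    thick <- if (length(cds)) c(start(cds) - 1L, end(cds))
             else c(chromStart, chromStart)
    paste(chrom(g), chromStart, max(end(ex)), txId(g), 0, geneStrand(g),
          thick[1], thick[2], "0", length(ex),
          paste0(paste(width(ex), collapse = ","), ","),
          paste0(paste(start(ex) - 1L - chromStart, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
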