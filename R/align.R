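#' @include AllClasses.R
#' @importFrom Biostrings PDict matchPDict matchPattern vmatchPattern startIndex
#'   neditStartingAt pairwiseAlignment nucleotideSubstitutionMatrix nmismatch
#'   score BStringSet
#' @importFrom Rsamtools asBam scanBam ScanBamParam
#' @importFrom utils head
NULL

## ---- FASTQ IO --------------------------------------------------------------

#' Read and write FASTQ
#'
#' Thin wrappers around Biostrings FASTQ support; read names are truncated at
#' the first whitespace.  \code{writeFastqReads} emits constant placeholder
#' qualities when none are supplied (the pipeline does not use base
#' qualities).
#'
#' @param path FASTQ file.
#' @param reads a named \code{DNAStringSet}.
#' @return \code{readFastqReads}: a named \code{DNAStringSet};
#'   \code{writeFastqReads}: \code{path}, invisibly.
#' @export
readFastqReads <- function(path) {
  reads <- readDNAStringSet(path, format = "fastq")
  names(reads) <- sub("\\s.*$", "", names(reads))
  reads
}

#' @rdname readFastqReads
#' @export
writeFastqReads <- function(reads, path) {
  quals <- BStringSet(strrep("I", width(reads)))
  writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

## ---- read trimming ---------------------------------------------------------

#' Trim reads from the 3' end
#'
#' Shortens every read by exactly \code{n} bases from the 3' end, the standard
#' remedy for poor base quality late in a sequencing cycle (e.g. 76 bp reads
#' trimmed by 40 bp yield 36 bp reads).
#'
#' @param reads a named \code{DNAStringSet}.
#' @param n bases to remove; must be smaller than every read length.
#' @return The trimmed \code{DNAStringSet}.
#' @export
trimReads <- function(reads, n) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  if (n == 0L) return(reads)
  bad <- which(width(reads) <= n)
  if (length(bad))
    stop("cannot trim ", n, " bp from read '", names(reads)[bad[1]],
         "' of length ", width(reads)[bad[1]])
  subseq(reads, 1L, width(reads) - n)
}

## ---- end-to-end alignment --------------------------------------------------

.emptyAlnDF <- function() {
  DataFrame(readId = character(), targetId = character(),
            start = integer(), end = integer(), strand = character(),
            mismatches = integer(), nBest = integer(), unique = logical(),
            mappedFully = logical())
}

## concatenate targets into one subject, separated by runs of N longer than
## the read, so one matchPattern call scans every target
.concatSubject <- function(targets, w) {
  sep <- paste(rep("N", w + 1L), collapse = "")
  parts <- as.character(targets)
  subject <- DNAString(paste(parts, collapse = sep))
  offsets <- cumsum(c(0L, head(width(targets), -1L) + w + 1L))
  list(subject = subject, offsets = offsets, lens = width(targets))
}

## all placements of one read in the concatenated subject (both strands),
## mapped back to per-target coordinates
.concatPlacements <- function(pattern, rcPattern, cs, targetNames, maxMM) {
  w <- length(pattern)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else rcPattern
    m <- matchPattern(pat, cs$subject, max.mismatch = maxMM)
    if (length(m) == 0L) next
    p <- start(m)
    p <- p[p >= 1L & p + w - 1L <= length(cs$subject)]
    if (!length(p)) next
    t <- findInterval(p, cs$offsets + 1L)
    st <- p - cs$offsets[t]
    keep <- st >= 1L & st + w - 1L <= cs$lens[t]
    if (!any(keep)) next
    p <- p[keep]; t <- t[keep]; st <- st[keep]
    mm <- neditStartingAt(pat, cs$subject, starting.at = p,
                          with.indels = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      targetId = targetNames[t], start = st, strand = strand,
      mismatches = as.integer(mm), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' End-to-end alignment of reads against a sequence collection
#'
#' A desk-scale substitute for a production genomic aligner: reports
#' full-length read placements (both strands) up to a configurable mismatch
#' budget, keeping only the placements at the minimal mismatch count for each
#' read.  A read is \emph{unique} when exactly one placement attains that
#' best count.  Reads with no placement are simply absent from the result;
#' use \code{unalignedReads} to recover them.  For real data, import
#' pre-computed alignments with \code{\link{importAlignments}} instead.
#'
#' @param reads named \code{DNAStringSet}.
#' @param targets named \code{DNAStringSet} (genome chromosomes, junction
#'   sequences, or transcripts); must be non-empty.
#' @param config a \code{\linkS4class{PipelineConfig}}; uses
#'   \code{maxMismatches}.
#' @return A \code{DataFrame} with one row per best placement: \code{readId},
#'   \code{targetId}, \code{start}, \code{end}, \code{strand},
#'   \code{mismatches}, \code{nBest}, \code{unique}, \code{mappedFully}.
#' @export
alignEndToEnd <- function(reads, targets, config = fusionConfig()) {
  if (length(targets) == 0L) stop("targets must be non-empty")
  if (length(reads) == 0L) return(.emptyAlnDF())
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must carry unique names")
  maxMM <- config@maxMismatches
  rcReads <- reverseComplement(reads)
  perRead <- vector("list", length(reads))
  names(perRead) <- names(reads)

  ## fast exact pass with a full-width PDict when all reads share one width
  exactDone <- rep(FALSE, length(reads))
  if (length(unique(width(reads))) == 1L && width(reads)[1] >= 20L) {
    hitAcc <- vector("list", length(reads))
    for (dir in c("+", "-")) {
      pd <- PDict(if (dir == "+") reads else rcReads)
      for (t in seq_along(targets)) {
        if (width(reads)[1] > width(targets)[t]) next
        m <- matchPDict(pd, targets[[t]])
        n <- elementNROWS(m)
        idx <- which(n > 0L)
        if (!length(idx)) next
        st <- startIndex(m)
        for (i in idx) {
          hitAcc[[i]] <- rbind(hitAcc[[i]], data.frame(
            targetId = names(targets)[t], start = st[[i]], strand = dir,
            mismatches = 0L, stringsAsFactors = FALSE))
        }
      }
    }
    exactDone <- !vapply(hitAcc, is.null, logical(1))
    perRead[exactDone] <- hitAcc[exactDone]
  }

  ## mismatch-tolerant scan of a concatenated subject for the remainder
  ## (a read with an exact placement already has its best score, 0)
  if (!all(exactDone) && maxMM >= 0L) {
    cs <- .concatSubject(targets, max(width(reads)))
    for (i in which(!exactDone)) {
      ## note: `[<-` with list(), not `[[<-`, so a NULL result cannot
      ## delete the element and shift read indices
      perRead[i] <- list(.concatPlacements(reads[[i]], rcReads[[i]], cs,
                                           names(targets), maxMM))
    }
  }

  rows <- vector("list", length(perRead))
  for (i in seq_along(perRead)) {
    h <- perRead[[i]]
    if (is.null(h) || nrow(h) == 0L) next
    best <- min(h$mismatches)
    h <- h[h$mismatches == best, , drop = FALSE]
    h$readId <- names(reads)[i]
    h$end <- as.integer(h$start + width(reads)[i] - 1L)
    h$nBest <- nrow(h)
    rows[[i]] <- h
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptyAlnDF())
  h <- do.call(rbind, rows)
  DataFrame(readId = h$readId, targetId = h$targetId,
            start = as.integer(h$start), end = h$end, strand = h$strand,
            mismatches = as.integer(h$mismatches), nBest = as.integer(h$nBest),
            unique = h$nBest == 1L, mappedFully = TRUE)
}

#' Reads absent from an alignment result
#'
#' @param reads named \code{DNAStringSet}.
#' @param alignments a \code{DataFrame} as returned by
#'   \code{\link{alignEndToEnd}}.
#' @return The subset of \code{reads} with no reported placement.
#' @export
unalignedReads <- function(reads, alignments) {
  reads[!names(reads) %in% unique(alignments$readId)]
}

## ---- local (partial) alignment ---------------------------------------------

.getSubMat <- function() {
  nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
}

#' Local alignment of reads against transcript sequences
#'
#' A surrogate for a Blat-style local aligner: computes the maximal-scoring
#' local alignment of each read against each target (both orientations) under
#' match +1, mismatch -1, gap -2 scoring, and reports blocks scoring at least
#' \code{minLocalScore}.  Read coordinates always refer to the read as given
#' (for minus-strand hits they are mapped back through the reverse
#' complement).
#'
#' @param reads named \code{DNAStringSet}.
#' @param targets named \code{DNAStringSet} of transcript sequences.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return \code{DataFrame}: \code{readId}, \code{targetId},
#'   \code{readStart}, \code{readEnd}, \code{targetStart}, \code{targetEnd},
#'   \code{strand}, \code{score}, \code{mismatches}.
#' @export
localAlign <- function(reads, targets, config = fusionConfig()) {
  mat <- .getSubMat()
  rows <- list()
  rcReads <- reverseComplement(reads)
  if (length(reads) == 0L || length(targets) == 0L) reads <- reads[0]
  for (t in seq_along(targets)) {
    perDir <- list()
    for (dir in c("+", "-")) {
      pats <- if (dir == "+") reads else rcReads
      if (!length(pats)) next
      al <- pairwiseAlignment(pats, targets[[t]], type = "local",
                              substitutionMatrix = mat,
                              gapOpening = 0, gapExtension = 2)
      sc <- score(al)
      w <- width(reads)
      ps <- start(al@pattern@range); pe <- end(al@pattern@range)
      flip <- dir == "-"
      if (flip) { tmp <- ps; ps <- w - pe + 1L; pe <- w - tmp + 1L }
      perDir[[dir]] <- DataFrame(
        readId = names(reads), targetId = names(targets)[t],
        readStart = as.integer(ps), readEnd = as.integer(pe),
        targetStart = as.integer(start(al@subject@range)),
        targetEnd = as.integer(end(al@subject@range)),
        strand = dir, score = sc, mismatches = nmismatch(al))
    }
    if (!length(perDir)) next
    ## best orientation per read for this target, then the score floor
    best <- perDir[["+"]]
    if (!is.null(perDir[["-"]])) {
      swap <- perDir[["-"]]$score > best$score
      best[swap, ] <- perDir[["-"]][swap, ]
    }
    best <- best[best$score >= config@minLocalScore, , drop = FALSE]
    if (nrow(best)) rows[[length(rows) + 1L]] <- best
  }
  if (!length(rows))
    return(DataFrame(readId = character(), targetId = character(),
                     readStart = integer(), readEnd = integer(),
                     targetStart = integer(), targetEnd = integer(),
                     strand = character(), score = numeric(),
                     mismatches = integer()))
  do.call(rbind, rows)
}

## ---- exact short-fragment matching -----------------------------------------

#' Exact placement of short fragments against exon sequences
#'
#' A surrogate for an exact short-read matcher: reports \emph{every} exact
#' full-length placement of each fragment in each target (both strands).
#' Fragments shorter than the configured floor are rejected with a warning,
#' bounding spurious hits from very short remainders.
#'
#' @param fragments named \code{DNAStringSet} (typically unaligned read
#'   remainders).
#' @param targets named \code{DNAStringSet} of exon sequences in transcript
#'   orientation.
#' @param config a \code{\linkS4class{PipelineConfig}}; uses
#'   \code{exactMinLen}.
#' @return \code{DataFrame}: \code{fragId}, \code{targetId}, \code{start},
#'   \code{end}, \code{strand}.
#' @export
exactShortAlign <- function(fragments, targets, config = fusionConfig()) {
  rows <- list()
  short <- which(width(fragments) < config@exactMinLen)
  if (length(short)) {
    warning(length(short), " fragment(s) below the ", config@exactMinLen,
            " bp exact-match floor were rejected")
    fragments <- fragments[-short]
  }
  rcFrags <- reverseComplement(fragments)
  for (i in seq_along(fragments)) {
    for (dir in c("+", "-")) {
      pat <- if (dir == "+") fragments[[i]] else rcFrags[[i]]
      m <- vmatchPattern(pat, targets, max.mismatch = 0)
      n <- elementNROWS(m)
      for (t in which(n > 0L)) {
        st <- start(m[[t]])
        rows[[length(rows) + 1L]] <- DataFrame(
          fragId = names(fragments)[i], targetId = names(targets)[t],
          start = as.integer(st),
          end = as.integer(st + width(fragments)[i] - 1L), strand = dir)
      }
    }
  }
  if (!length(rows))
    return(DataFrame(fragId = character(), targetId = character(),
                     start = integer(), end = integer(), strand = character()))
  do.call(rbind, rows)
}

## ---- SAM/BAM import and export ---------------------------------------------

#' Import genomic alignments from SAM/BAM
#'
#' Reads pre-computed alignments in place of the built-in aligner.  A record
#' is \emph{unique} when its MAPQ is at least \code{mapqFloor} and it is not a
#' secondary alignment; it is \emph{fully mapped} when its CIGAR is a single
#' match run spanning the whole read.
#'
#' @param path SAM (text) or BAM file.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return \code{DataFrame}: \code{readId}, \code{mate} (1, 2 or NA),
#'   \code{targetId}, \code{start}, \code{end}, \code{strand},
#'   \code{mismatches}, \code{unique}, \code{mappedFully}.
#' @export
importAlignments <- function(path, config = fusionConfig()) {
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    dest <- tempfile(fileext = "")
    tryCatch(Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
             error = function(e) stop("malformed SAM '", path, "': ",
                                      conditionMessage(e)))
  } else path
  p <- ScanBamParam(what = c("qname", "flag", "rname", "strand", "pos",
                             "mapq", "cigar", "qwidth"),
                    tag = "NM")
  b <- scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(b$qname))
  nm[is.na(nm)] <- 0L
  mate <- ifelse(bitwAnd(b$flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(b$flag, 128L) > 0L, 2L, NA_integer_))
  secondary <- bitwAnd(b$flag, 256L) > 0L
  fullM <- !is.na(b$cigar) & grepl("^[0-9]+M$", b$cigar)
  keep <- which(mapped)
  DataFrame(readId = b$qname[keep], mate = mate[keep],
            targetId = as.character(b$rname)[keep],
            start = b$pos[keep],
            end = b$pos[keep] + b$qwidth[keep] - 1L,
            strand = as.character(b$strand)[keep],
            mismatches = as.integer(nm)[keep],
            unique = b$mapq[keep] >= config@mapqFloor & !secondary[keep],
            mappedFully = fullM[keep])
}

#' Write paired-end alignments as a minimal SAM file
#'
#' Serializes built-in aligner results (unique placements only) so that the
#' import path and the built-in path can be compared on identical data.
#'
#' @param pairs a pair table from \code{\link{pairAlignments}}.
#' @param reads1,reads2 the mate sequences (named \code{DNAStringSet}).
#' @param targets the reference the alignments refer to.
#' @param path output SAM path.
#' @return \code{path}, invisibly.
#' @export
writeSAM <- function(pairs, reads1, reads2, targets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (t in seq_along(targets))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(targets)[t],
                       width(targets)[t]), con)
  emit <- function(id, mateNo, chrom, pos, strand, mm, mchrom, mpos, mstrand,
                   seqs) {
    flag <- 1L + 2L + (if (mateNo == 1L) 64L else 128L)
    if (strand == "-") flag <- flag + 16L
    if (mstrand == "-") flag <- flag + 32L
    sq <- as.character(seqs[[id]])
    if (strand == "-") sq <- as.character(reverseComplement(DNAString(sq)))
    writeLines(paste(id, flag, chrom, pos, 60L, paste0(nchar(sq), "M"),
                     if (chrom == mchrom) "=" else mchrom, mpos, 0L, sq,
                     strrep("I", nchar(sq)), paste0("NM:i:", mm),
                     sep = "\t"), con)
  }
  for (k in seq_len(nrow(pairs))) {
    r <- pairs[k, ]
    emit(r$pairId, 1L, r$chrom1, r$start1, r$strand1, r$mm1,
         r$chrom2, r$start2, r$strand2, reads1)
    emit(r$pairId, 2L, r$chrom2, r$start2, r$strand2, r$mm2,
         r$chrom1, r$start1, r$strand1, reads2)
  }
  invisible(path)
}

#' Join per-mate alignments into a pair table
#'
#' Combines the unique best placements of mate 1 and mate 2 (same read ids in
#' both sets) into one row per pair.  Pairs with an unaligned mate (orphans)
#' are skipped and counted in the \code{"orphans"} attribute.
#'
#' @param aln1,aln2 \code{DataFrame}s from \code{\link{alignEndToEnd}} for
#'   mate 1 and mate 2.
#' @return \code{DataFrame}: \code{pairId}, \code{chrom1}, \code{start1},
#'   \code{strand1}, \code{mm1}, \code{unique1}, \code{full1}, and the same
#'   for mate 2.
#' @export
pairAlignments <- function(aln1, aln2) {
  pick <- function(df) {
    df <- df[df$unique & df$mappedFully, , drop = FALSE]
    df[!duplicated(df$readId), , drop = FALSE]
  }
  a1 <- pick(aln1); a2 <- pick(aln2)
  ids <- intersect(a1$readId, a2$readId)
  orphans <- length(union(aln1$readId, aln2$readId)) - length(ids)
  i1 <- match(ids, a1$readId); i2 <- match(ids, a2$readId)
  out <- DataFrame(pairId = ids,
                   chrom1 = a1$targetId[i1], start1 = a1$start[i1],
                   strand1 = a1$strand[i1], mm1 = a1$mismatches[i1],
                   unique1 = a1$unique[i1], full1 = a1$mappedFully[i1],
                   chrom2 = a2$targetId[i2], start2 = a2$start[i2],
                   strand2 = a2$strand[i2], mm2 = a2$mismatches[i2],
                   unique2 = a2$unique[i2], full2 = a2$mappedFully[i2])
  attr(out, "orphans") <- orphans
  out
}

#' Build a pair table from imported SAM/BAM records
#'
#' @param aln a \code{DataFrame} from \code{\link{importAlignments}} with a
#'   \code{mate} column.
#' @return A pair table as from \code{\link{pairAlignments}}.
#' @export
importedPairs <- function(aln) {
  pairAlignments(aln[!is.na(aln$mate) & aln$mate == 1L, , drop = FALSE],
                 aln[!is.na(aln$mate) & aln$mate == 2L, , drop = FALSE])
}
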