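#' @include AllClasses.R annotation.R
#' @importFrom stats rnorm rbinom
NULL

#' Specification of a simulated fusion-bearing RNA-Seq experiment
#'
#' Declares the toy genome (chromosome count and length, gene count, exon
#' geometry), the fusion events to inject, and the sequencing regime
#' (single- or paired-end, read length, fragment size, substitution error
#' rate, PCR-duplicate fraction, depth).  Every derived output is
#' deterministic for a fixed \code{seed}.
#'
#' @slot seed integer random seed.
#' @slot nChromosomes,chromLength,nGenes genome geometry.
#' @slot exonCountRange,exonLengthRange,intronLengthRange integer(2) sampling
#'   ranges per gene.
#' @slot fusions data.frame of events: \code{gene5}, \code{exon5},
#'   \code{gene3}, \code{exon3}, \code{multiplier} (fusion transcript
#'   abundance relative to a wild-type transcript), \code{reciprocal}
#'   (also emit the reciprocal-product transcript), \code{junctionPairs}
#'   (NA, or an exact number of junction-flanking read pairs to emit).
#' @slot readMode \code{"se"} or \code{"pe"}.
#' @slot readLength,fragmentMean,fragmentSd read/fragment geometry in bp.
#' @slot errorRate per-base substitution probability.
#' @slot duplicateFraction fraction of fragments re-emitted with identical
#'   coordinates (PCR duplicates).
#' @slot depth mean fold-coverage of the transcript pool.
#' @export
setClass("SimulationSpec",
  representation(
    seed = "integer", nChromosomes = "integer", chromLength = "integer",
    nGenes = "integer", exonCountRange = "integer",
    exonLengthRange = "integer", intronLengthRange = "integer",
    fusions = "data.frame", readMode = "character", readLength = "integer",
    fragmentMean = "numeric", fragmentSd = "numeric", errorRate = "numeric",
    duplicateFraction = "numeric", depth = "numeric"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@errorRate < 0 || object@errorRate > 1 ||
      object@duplicateFraction < 0 || object@duplicateFraction > 1)
    msg <- c(msg, "rates must lie in [0, 1]")
  if (!object@readMode %in% c("se", "pe"))
    msg <- c(msg, "readMode must be 'se' or 'pe'")
  if (object@readMode == "pe" && object@readLength >= object@fragmentMean)
    msg <- c(msg, "read length must be below the mean fragment size for PE")
  if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
  if (object@nGenes < 1 || object@nChromosomes < 1)
    msg <- c(msg, "need at least one gene and one chromosome")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationSpec
#'
#' Defaults emulate a desk-scale version of the target data regime: 50 bp
#' reads, ~250 bp paired-end fragments, a low substitution error rate, a
#' small PCR-duplicate fraction, and a toy multi-chromosome genome of
#' multi-exon genes.
#'
#' @param seed,nChromosomes,chromLength,nGenes,exonCountRange,exonLengthRange,intronLengthRange
#'   genome geometry; see \code{\linkS4class{SimulationSpec}}.
#' @param fusions data.frame of fusion events (possibly empty);
#'   \code{fusionEvent} builds one row.
#' @param readMode,readLength,fragmentMean,fragmentSd,errorRate,duplicateFraction,depth
#'   sequencing regime.
#' @return A validated \code{\linkS4class{SimulationSpec}}.
#' @examples
#' spec <- simulationSpec(seed = 7, fusions = fusionEvent("GENE001", 2, "GENE004", 3))
#' @export
simulationSpec <- function(seed = 1L, nChromosomes = 2L, chromLength = 30000L,
                           nGenes = 6L, exonCountRange = c(3L, 6L),
                           exonLengthRange = c(80L, 220L),
                           intronLengthRange = c(100L, 400L),
                           fusions = fusionEvent()[0, ],
                           readMode = "pe", readLength = 50L,
                           fragmentMean = 250, fragmentSd = 25,
                           errorRate = 0.005, duplicateFraction = 0.05,
                           depth = 10) {
  new("SimulationSpec", seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
      exonCountRange = as.integer(exonCountRange),
      exonLengthRange = as.integer(exonLengthRange),
      intronLengthRange = as.integer(intronLengthRange),
      fusions = fusions, readMode = readMode,
      readLength = as.integer(readLength), fragmentMean = fragmentMean,
      fragmentSd = fragmentSd, errorRate = errorRate,
      duplicateFraction = duplicateFraction, depth = depth)
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec (seed %d): %d chrom x %d bp, %d genes, %s %d bp reads, depth %gx\n",
              object@seed, object@nChromosomes, object@chromLength,
              object@nGenes, toupper(object@readMode), object@readLength,
              object@depth))
  cat(sprintf("  %d fusion event(s); error rate %g; duplicate fraction %g\n",
              nrow(object@fusions), object@errorRate, object@duplicateFraction))
})

#' Declare fusion events for the simulator
#'
#' @param gene5,gene3 partner gene ids (e.g. \code{"GENE001"}).
#' @param exon5 last exon of the 5' partner retained in the fusion.
#' @param exon3 first exon of the 3' partner retained.
#' @param multiplier fusion transcript abundance relative to one wild-type
#'   transcript (drives 3'-partner overexpression downstream of the
#'   breakpoint).
#' @param reciprocal also emit the reciprocal product (partners' roles
#'   exchanged around the same breakpoint).
#' @param junctionPairs NA, or an exact number of junction-flanking read
#'   pairs to emit (both mates clear of the junction), for controlled
#'   pair-coverage experiments.
#' @return A one-row data.frame; rbind rows for multiple events.
#' @export
fusionEvent <- function(gene5 = character(), exon5 = integer(),
                        gene3 = character(), exon3 = integer(),
                        multiplier = 1, reciprocal = FALSE,
                        junctionPairs = NA_integer_) {
  n <- length(gene5)
  data.frame(gene5 = as.character(gene5), exon5 = as.integer(exon5),
             gene3 = as.character(gene3), exon3 = as.integer(exon3),
             multiplier = rep_len(as.numeric(multiplier), n),
             reciprocal = rep_len(as.logical(reciprocal), n),
             junctionPairs = rep_len(as.integer(junctionPairs), n),
             stringsAsFactors = FALSE)
}

.randomDNA <- function(n) {
  DNAString(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""))
}

## transcript -> genomic position for CDS placement
.txToGenomic <- function(gene, p) {
  ends <- txExonEnds(gene)
  before <- c(0L, head(ends, -1L))
  k <- which(p <= ends)[1]
  off <- p - before[k]
  ex <- exons(gene)
  if (geneStrand(gene) == "+") start(ex)[k] + off - 1L
  else end(ex)[k] - off + 1L
}

#' Generate a toy reference genome and annotation
#'
#' Draws random chromosome sequences and packs non-overlapping multi-exon
#' genes onto them (random strand), assigning each gene a CDS whose 5' and 3'
#' UTRs leave both in-frame and out-of-frame fusions constructible.
#' Deterministic for a fixed seed; an infeasible packing is an error
#' suggesting longer chromosomes.
#'
#' @param spec a \code{\linkS4class{SimulationSpec}}.
#' @return list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{genes} (\code{\linkS4class{GeneModelList}}).
#' @export
generateReference <- function(spec) {
  set.seed(spec@seed)
  genome <- DNAStringSet(lapply(seq_len(spec@nChromosomes),
                                function(i) .randomDNA(spec@chromLength)))
  names(genome) <- sprintf("chr%d", seq_len(spec@nChromosomes))
  chromOf <- rep(seq_len(spec@nChromosomes), length.out = spec@nGenes)
  cursor <- rep(1L, spec@nChromosomes)
  models <- list()
  for (i in seq_len(spec@nGenes)) {
    ch <- chromOf[i]
    nEx <- sample(spec@exonCountRange[1]:spec@exonCountRange[2], 1L)
    exLens <- sample(spec@exonLengthRange[1]:spec@exonLengthRange[2], nEx,
                     replace = TRUE)
    inLens <- sample(spec@intronLengthRange[1]:spec@intronLengthRange[2],
                     max(nEx - 1L, 0L), replace = TRUE)
    gStart <- cursor[ch] + sample(200:500, 1L)
    span <- sum(exLens) + sum(inLens)
    if (gStart + span > spec@chromLength - 200L)
      stop("infeasible gene packing on ", names(genome)[ch],
           "; increase chromLength or reduce nGenes")
    starts <- integer(nEx); ends <- integer(nEx)
    pos <- gStart
    for (k in seq_len(nEx)) {
      starts[k] <- pos
      ends[k] <- pos + exLens[k] - 1L
      pos <- ends[k] + 1L + (if (k < nEx) inLens[k] else 0L)
    }
    cursor[ch] <- ends[nEx]
    strand <- sample(c("+", "-"), 1L)
    gm <- geneModel(sprintf("GENE%03d", i), names(genome)[ch], strand,
                    IRanges(starts, ends))
    ## CDS: UTRs inside the terminal exons, CDS length a multiple of 3
    L <- txLength(gm)
    utr5 <- sample(10:40, 1L)
    utr3 <- sample(10:40, 1L)
    cdsLen <- L - utr5 - utr3
    cdsLen <- cdsLen - (cdsLen %% 3L)
    g1 <- .txToGenomic(gm, utr5 + 1L)
    g2 <- .txToGenomic(gm, utr5 + cdsLen)
    models[[i]] <- geneModel(geneId(gm), chrom(gm), strand,
                             exons(gm), cds = range(c(g1, g2)))
  }
  list(genome = genome, genes = GeneModelList(models))
}

#' Inject fusion transcripts and record the truth
#'
#' For each event, builds the fusion transcript joining exons 1..exon5 of the
#' 5' partner with exons exon3..last of the 3' partner (transcript
#' orientation), plus the reciprocal product when flagged, and records the
#' truth: partner genes, junction exons, the junction position on the fusion
#' transcript, the expected junction sequence (read directly off the fusion
#' transcript), and whether the breakpoint lies in the 5' partner's 5' UTR.
#'
#' @param ref output of \code{\link{generateReference}}.
#' @param spec the \code{\linkS4class{SimulationSpec}} carrying the events.
#' @return list with \code{transcripts} (named \code{DNAStringSet}) and
#'   \code{truth} (data.frame, one row per emitted fusion transcript).
#' @export
injectFusion <- function(ref, spec) {
  events <- spec@fusions
  x <- spec@readLength
  txs <- list(); truth <- list()
  addEvent <- function(g5, e5, g3, e3, multiplier, junctionPairs) {
    m5 <- .modelsForGene(ref$genes, g5)
    m3 <- .modelsForGene(ref$genes, g3)
    if (!length(m5) || !length(m3)) stop("unknown fusion partner gene")
    m5 <- m5[[1]]; m3 <- m3[[1]]
    if (e5 < 1L || e5 > nExons(m5) || e3 < 1L || e3 > nExons(m3))
      stop("fusion exon ordinal out of range for ", g5, "/", g3)
    s5 <- exonSequences(m5, ref$genome)[seq_len(e5)]
    s3 <- exonSequences(m3, ref$genome)[e3:nExons(m3)]
    fus <- unlist(c(s5, s3))
    id <- sprintf("FUS|%s|%d|%s|%d", g5, e5, g3, e3)
    junctionPos <- sum(width(s5))
    leftArm <- min(x - 5L, width(s5)[e5])
    rightArm <- min(x - 5L, width(s3)[1])
    jseq <- as.character(subseq(fus, junctionPos - leftArm + 1L,
                                junctionPos + rightArm))
    cds5 <- .cdsTxStart(m5)
    txs[[id]] <<- fus
    truth[[length(truth) + 1L]] <<- data.frame(
      fusionId = id, gene5 = g5, exon5 = e5, gene3 = g3, exon3 = e3,
      junctionPos = junctionPos, junctionSeq = jseq,
      utrTruncation = !is.na(cds5) && junctionPos < cds5,
      multiplier = multiplier, junctionPairs = junctionPairs,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    addEvent(ev$gene5, ev$exon5, ev$gene3, ev$exon3, ev$multiplier,
             ev$junctionPairs)
    if (isTRUE(ev$reciprocal)) {
      m5 <- .modelsForGene(ref$genes, ev$gene5)[[1]]
      m3 <- .modelsForGene(ref$genes, ev$gene3)[[1]]
      if (ev$exon3 - 1L < 1L || ev$exon5 + 1L > nExons(m5))
        stop("reciprocal event has no exons to exchange")
      addEvent(ev$gene3, ev$exon3 - 1L, ev$gene5, ev$exon5 + 1L,
               ev$multiplier, NA_integer_)
    }
  }
  transcripts <- DNAStringSet(txs)
  list(transcripts = transcripts,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(fusionId = character(), gene5 = character(),
                    exon5 = integer(), gene3 = character(), exon3 = integer(),
                    junctionPos = integer(), junctionSeq = character(),
                    utrTruncation = logical(), multiplier = numeric(),
                    junctionPairs = integer(), stringsAsFactors = FALSE))
}

## substitute bases i.i.d. at `rate`; always to a different base
.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- length(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  s <- strsplit(as.character(seq), "")[[1]]
  for (p in pos) {
    s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  }
  DNAString(paste(s, collapse = ""))
}

#' Simulate RNA-Seq reads from a transcript pool
#'
#' Samples fragments from the wild-type transcripts (weight 1 each) and any
#' fusion transcripts (weight = the event's abundance multiplier) in
#' proportion to weight x length, emits single-end reads or standard
#' forward/reverse paired-end mates, applies i.i.d. substitution errors,
#' re-emits a fraction of fragments at identical coordinates as PCR
#' duplicates, and records per-read provenance.  Events with an exact
#' \code{junctionPairs} count additionally emit precisely that many
#' junction-flanking pairs (both mates clear of the junction).
#' Deterministic for the spec's seed.
#'
#' @param spec a \code{\linkS4class{SimulationSpec}}.
#' @param ref output of \code{\link{generateReference}}.
#' @param fusions optional output of \code{\link{injectFusion}}.
#' @return list with \code{reads} (SE: named \code{DNAStringSet}; PE: list of
#'   \code{mate1}, \code{mate2}) and \code{provenance} (data.frame:
#'   \code{readId}, \code{source}, \code{start}, \code{fragLen},
#'   \code{isDuplicate}, \code{dupOf}, \code{category}).
#' @export
simulateReads <- function(spec, ref, fusions = NULL) {
  set.seed((spec@seed + 7919L) %% .Machine$integer.max)
  x <- spec@readLength
  pe <- spec@readMode == "pe"
  pool <- transcriptSequences(ref$genes, ref$genome)
  weights <- rep(1, length(pool))
  categories <- rep("wild_type", length(pool))
  truth <- NULL
  if (!is.null(fusions) && length(fusions$transcripts)) {
    pool <- c(pool, fusions$transcripts)
    weights <- c(weights, fusions$truth$multiplier)
    categories <- c(categories, rep("fusion", length(fusions$transcripts)))
    truth <- fusions$truth
  }
  lens <- width(pool)
  nMates <- if (pe) 2L else 1L
  nFrag <- max(1L, round(spec@depth * sum(weights * lens) / (x * nMates)))
  prob <- weights * lens / sum(weights * lens)
  srcIdx <- sample.int(length(pool), nFrag, replace = TRUE, prob = prob)

  drawFrag <- function(tl) {
    if (!pe) return(x)
    for (try in 1:100) {
      L <- max(x, round(rnorm(1, spec@fragmentMean, spec@fragmentSd)))
      if (L <= tl) return(L)
    }
    stop("fragment repeatedly longer than transcript (", tl,
         " bp); reduce fragmentMean")
  }

  frag <- data.frame(src = srcIdx, start = NA_integer_, len = NA_integer_,
                     category = categories[srcIdx], stringsAsFactors = FALSE)
  for (i in seq_len(nFrag)) {
    tl <- lens[frag$src[i]]
    if (tl < x) stop("transcript shorter than the read length")
    L <- drawFrag(tl)
    frag$len[i] <- L
    frag$start[i] <- sample.int(tl - L + 1L, 1L)
  }

  ## controlled junction-flanking pairs for events that request them
  if (pe && !is.null(truth) && any(!is.na(truth$junctionPairs))) {
    for (k in which(!is.na(truth$junctionPairs))) {
      J <- truth$junctionPos[k]
      src <- match(truth$fusionId[k], names(pool))
      tl <- lens[src]
      ## exon-segment boundaries of the fusion transcript, so each flanking
      ## mate can be placed wholly inside one exon (and thus map fully and
      ## uniquely to the genome)
      m5 <- .modelsForGene(ref$genes, truth$gene5[k])[[1]]
      m3 <- .modelsForGene(ref$genes, truth$gene3[k])[[1]]
      segs <- c(width(exons(m5))[seq_len(truth$exon5[k])],
                width(exons(m3))[truth$exon3[k]:nExons(m3)])
      segEnd <- cumsum(segs)
      segStart <- c(1L, head(segEnd, -1L) + 1L)
      insideExon <- function(a, b) {        # interval [a, b] within one exon
        any(a >= segStart & b <= segEnd)
      }
      for (r in seq_len(truth$junctionPairs[k])) {
        ok <- FALSE
        for (try in 1:200) {
          L <- max(2L * x + 2L, round(rnorm(1, spec@fragmentMean, spec@fragmentSd)))
          if (L > tl) next
          sCand <- seq_len(tl - L + 1L)
          sCand <- sCand[sCand + x - 1L <= J & sCand + L - x >= J + 1L]
          sCand <- sCand[vapply(sCand, function(s)
            insideExon(s, s + x - 1L) && insideExon(s + L - x, s + L - 1L),
            logical(1))]
          if (length(sCand)) {
            s <- if (length(sCand) == 1L) sCand else sample(sCand, 1L)
            frag <- rbind(frag, data.frame(src = src, start = s, len = L,
                                           category = "junction_pair",
                                           stringsAsFactors = FALSE))
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place a junction-flanking fragment; ",
                      "fragment size incompatible with the transcript")
      }
    }
  }

  ## PCR duplicates: re-emit a fraction of fragments at identical coordinates
  nDup <- round(spec@duplicateFraction * nrow(frag))
  dupOf <- rep(NA_integer_, nrow(frag))
  if (nDup > 0L) {
    originals <- sample.int(nrow(frag), nDup)
    dupRows <- frag[originals, , drop = FALSE]
    frag <- rbind(frag, dupRows)
    dupOf <- c(dupOf, originals)
  }

  ids <- sprintf("r%06d", seq_len(nrow(frag)))
  m1 <- vector("list", nrow(frag)); m2 <- vector("list", nrow(frag))
  se <- vector("list", nrow(frag))
  seStrand <- character(nrow(frag))
  for (i in seq_len(nrow(frag))) {
    tx <- pool[[frag$src[i]]]
    s <- frag$start[i]; L <- frag$len[i]
    if (pe) {
      m1[[i]] <- .mutate(subseq(tx, s, s + x - 1L), spec@errorRate)
      m2[[i]] <- .mutate(reverseComplement(subseq(tx, s + L - x, s + L - 1L)),
                         spec@errorRate)
    } else {
      rd <- subseq(tx, s, s + x - 1L)
      if (sample(c(TRUE, FALSE), 1L)) {
        rd <- reverseComplement(rd); seStrand[i] <- "-"
      } else seStrand[i] <- "+"
      se[[i]] <- .mutate(rd, spec@errorRate)
    }
  }
  prov <- data.frame(readId = ids, source = names(pool)[frag$src],
                     start = frag$start, fragLen = frag$len,
                     isDuplicate = !is.na(dupOf),
                     dupOf = ifelse(is.na(dupOf), NA_character_, ids[dupOf]),
                     category = frag$category, stringsAsFactors = FALSE)
  if (pe) {
    mate1 <- DNAStringSet(m1); mate2 <- DNAStringSet(m2)
    names(mate1) <- names(mate2) <- ids
    list(reads = list(mate1 = mate1, mate2 = mate2), provenance = prov)
  } else {
    reads <- DNAStringSet(se)
    names(reads) <- ids
    prov$strand <- seStrand
    list(reads = reads, provenance = prov)
  }
}
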