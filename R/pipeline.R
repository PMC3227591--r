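#' @include AllClasses.R align.R se_fusion.R pe_fusion.R
#' @importFrom jsonlite write_json
NULL

## configuration snapshot for manifests
.configAsList <- function(config) {
  sl <- slotNames(config)
  out <- lapply(sl, function(s) slot(config, s))
  names(out) <- sl
  out
}

#' Run manifest
#'
#' Captures what a pipeline run did: the command, a configuration snapshot,
#' input digests, seed, package version, timestamp, and per-stage counts
#' (which are non-increasing through successive filters).
#'
#' @param command short command name.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @param counts named list of per-stage read/pair/candidate counts.
#' @param inputs named character vector of input file paths (digested when
#'   they exist).
#' @param seed integer seed, if any randomness was involved.
#' @return A list of class \code{"runManifest"}.
#' @export
runManifest <- function(command, config, counts = list(), inputs = character(),
                        seed = NA_integer_) {
  digests <- if (length(inputs))
    vapply(inputs, function(f)
      if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
      character(1))
  else character()
  structure(list(command = command, config = .configAsList(config),
                 inputs = as.list(digests), seed = seed,
                 version = as.character(utils::packageVersion("fusionfindR")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 counts = counts),
            class = "runManifest")
}

#' @export
print.runManifest <- function(x, ...) {
  cat("Run manifest:", x$command, "(fusionfindR", x$version, ")\n")
  for (n in names(x$counts)) cat(sprintf("  %-28s %s\n", n, x$counts[[n]]))
  invisible(x)
}

#' Write a run manifest as JSON
#' @param manifest a \code{\link{runManifest}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Paired-end fusion discovery pipeline
#'
#' Runs the full paired-end workflow: genomic alignment of both mates (or a
#' supplied pair table from SAM/BAM import), splice-junction rescue of
#' unmapped reads, discordant-pair selection, gene assignment, PEFS scoring,
#' prioritization, junction-spanning confirmation against the pairwise
#' fusion-junction library, and the in-frame call.
#'
#' @param reads1,reads2 named \code{DNAStringSet}s of mates (same names).
#' @param genes a \code{\linkS4class{GeneModelList}}.
#' @param genome named \code{DNAStringSet}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @param pairs optional pre-computed pair table
#'   (\code{\link{importedPairs}}); when given, genomic alignment is skipped
#'   and reads are used only for junction rescue and spanning search.
#' @return list: \code{candidates} (prioritized, confirmed
#'   \code{\linkS4class{FusionCandidate}}s), \code{allCandidates},
#'   \code{manifest}, \code{unmappedPool}.
#' @export
detectFusionsPE <- function(reads1, reads2, genes, genome,
                            config = fusionConfig(), pairs = NULL) {
  if (!identical(names(reads1), names(reads2)))
    stop("mate sets must carry identical read names in order")
  spliceLib <- buildSpliceJunctionLibrary(genes, genome, config@readLength)
  if (is.null(pairs)) {
    aln1 <- alignEndToEnd(reads1, genome, config)
    aln2 <- alignEndToEnd(reads2, genome, config)
    pairs <- pairAlignments(aln1, aln2)
    genomeMapped1 <- unique(aln1$readId); genomeMapped2 <- unique(aln2$readId)
  } else {
    genomeMapped1 <- pairs$pairId; genomeMapped2 <- pairs$pairId
  }
  ## unmapped pool: mate reads with no genomic placement, minus those
  ## explained by ordinary splice junctions
  pool <- DNAStringSet()
  if (length(reads1)) {
    pool <- c(`names<-`(reads1, paste0(names(reads1), "/1")),
              `names<-`(reads2, paste0(names(reads2), "/2")))
    pool <- pool[!names(pool) %in% c(paste0(genomeMapped1, "/1"),
                                     paste0(genomeMapped2, "/2"))]
  }
  if (length(pool) && length(junctionSeqs(spliceLib))) {
    spliceAln <- alignEndToEnd(pool, junctionSeqs(spliceLib), config)
    pool <- unalignedReads(pool, spliceAln)
  }
  discordant <- selectDiscordantPairs(pairs, config)
  assigned <- assignPairsToGenes(discordant, reads1, reads2, genes, genome,
                                 config)
  allCand <- buildCandidates(assigned, config)
  prio <- prioritizeCandidates(allCand, config)
  prio <- lapply(prio, function(cand) {
    cand <- findSpanningReads(cand, pool, genes, genome, config)
    if (!anyNA(cand@predictedJunction))
      cand <- determineInFrame(cand, genes)
    cand
  })
  manifest <- runManifest("detect-pe", config, counts = list(
    totalPairs = length(reads1),
    bothMatesMapped = nrow(pairs),
    discordantPairs = nrow(discordant),
    geneAssignedPairs = length(unique(assigned$pairId)),
    candidates = length(allCand),
    prioritized = length(prio)))
  list(candidates = prio, allCandidates = allCand, manifest = manifest,
       unmappedPool = pool)
}

#' Single-end fusion discovery pipeline
#'
#' Genomic alignment, splice-junction rescue, then the GFCR workflow: partial
#' transcript alignment (group A), exact remainder placement at exon ends
#' (group B), GFCR assembly and candidate calling.
#'
#' @param reads named \code{DNAStringSet}.
#' @param genes a \code{\linkS4class{GeneModelList}}.
#' @param genome named \code{DNAStringSet}.
#' @param config a \code{\linkS4class{PipelineConfig}}.
#' @return list: \code{candidates} (\code{DataFrame}), \code{gfcrs},
#'   \code{groupA}, \code{manifest}, \code{unmappedPool}.
#' @export
detectFusionsSE <- function(reads, genes, genome, config = fusionConfig()) {
  aln <- alignEndToEnd(reads, genome, config)
  pool <- unalignedReads(reads, aln)
  spliceLib <- buildSpliceJunctionLibrary(genes, genome, config@readLength)
  if (length(pool) && length(junctionSeqs(spliceLib))) {
    spliceAln <- alignEndToEnd(pool, junctionSeqs(spliceLib), config)
    pool <- unalignedReads(pool, spliceAln)
  }
  groupA <- findGroupA(pool, genes, genome, config)
  groupB <- findGroupB(groupA, pool, genes, genome, config)
  gfcrs <- combineToGFCR(groupA, groupB)
  candidates <- callSECandidates(gfcrs, config)
  manifest <- runManifest("detect-se", config, counts = list(
    totalReads = length(reads),
    unmappedReads = length(pool),
    groupAHits = nrow(groupA),
    gfcrs = nrow(gfcrs),
    candidates = nrow(candidates)))
  list(candidates = candidates, gfcrs = gfcrs, groupA = groupA,
       manifest = manifest, unmappedPool = pool)
}

#' Tabulate fusion candidates
#'
#' @param candidates list of \code{\linkS4class{FusionCandidate}}.
#' @return data.frame, one row per candidate: gene5, gene3, P, D, M, pefs,
#'   nSpanning, predictedJunction (\code{"e5>e3"}), isoforms
#'   (\code{";"}-separated), inFrame.
#' @export
candidateTable <- function(candidates) {
  if (!length(candidates))
    return(data.frame(gene5 = character(), gene3 = character(),
                      P = integer(), D = integer(), M = integer(),
                      pefs = numeric(), nSpanning = integer(),
                      predictedJunction = character(), isoforms = character(),
                      inFrame = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(candidates, function(x) {
    pj <- if (anyNA(predictedJunction(x))) "unconfirmed"
          else sprintf("%d>%d", predictedJunction(x)[1], predictedJunction(x)[2])
    iso <- if (nrow(isoforms(x)))
      paste(sprintf("%d>%d", isoforms(x)$exon5, isoforms(x)$exon3),
            collapse = ";")
    else ""
    data.frame(gene5 = x@gene5, gene3 = x@gene3, P = supportCount(x),
               D = duplicateCount(x), M = mismatchCount(x), pefs = pefs(x),
               nSpanning = nrow(spanningReads(x)), predictedJunction = pj,
               isoforms = iso,
               inFrame = ifelse(is.na(inFrame(x)), "NA", inFrame(x)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write the candidate report
#'
#' \code{writeCandidateTable} emits the TSV summary;
#' \code{writeCandidateJSON} the per-candidate detail (supporting pair and
#' spanning read ids).
#'
#' @param candidates list of \code{\linkS4class{FusionCandidate}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCandidateTable <- function(candidates, path) {
  utils::write.table(candidateTable(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidateTable
#' @export
writeCandidateJSON <- function(candidates, path) {
  detail <- lapply(candidates, function(x) list(
    gene5 = x@gene5, gene3 = x@gene3, pefs = pefs(x),
    supportPairs = as.list(as.data.frame(x@supportPairs)),
    spanningReads = as.list(as.data.frame(spanningReads(x))),
    predictedJunction = predictedJunction(x),
    inFrame = inFrame(x)))
  jsonlite::write_json(detail, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
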