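## build a minimal pair table row
mkPair <- function(id, c1, s1, c2, s2, st1 = "+", st2 = "-", mm1 = 0L,
                   mm2 = 0L, uniq = TRUE, full = TRUE) {
  DataFrame(pairId = id, chrom1 = c1, start1 = as.integer(s1), strand1 = st1,
            mm1 = as.integer(mm1), unique1 = uniq, full1 = full,
            chrom2 = c2, start2 = as.integer(s2), strand2 = st2,
            mm2 = as.integer(mm2), unique2 = uniq, full2 = full)
}

## build an assigned-pairs table for candidate construction
mkAssigned <- function(g5, g3, starts1, starts2, mm1 = 0L, mm2 = 0L) {
  n <- length(starts1)
  DataFrame(pairId = sprintf("p%03d", seq_len(n)), gene5 = g5, gene3 = g3,
            chrom1 = "chr1", start1 = as.integer(starts1),
            strand1 = "+", mm1 = as.integer(rep_len(mm1, n)),
            chrom2 = "chr2", start2 = as.integer(starts2), strand2 = "-",
            mm2 = as.integer(rep_len(mm2, n)),
            category = "interchromosomal", ambiguousOrientation = FALSE)
}

test_that("discordant pair selection applies the category rules", {
  pairs <- rbind(
    mkPair("inter", "chr1", 100, "chr11", 5000),
    mkPair("near", "chr3", 1e6, "chr3", 1.5e6),        # 0.5 Mb apart
    mkPair("far", "chr3", 1e6, "chr3", 2.5e6),         # 1.5 Mb apart
    mkPair("multi", "chr1", 100, "chr2", 100, uniq = FALSE),
    mkPair("concord", "chr2", 1000, "chr2", 1250))
  disc <- selectDiscordantPairs(pairs, fusionConfig())
  expect_setequal(disc$pairId, c("inter", "far"))
  expect_identical(disc$category[disc$pairId == "inter"], "interchromosomal")
  expect_identical(disc$category[disc$pairId == "far"], "long_intrachromosomal")
})

test_that("PEFS evaluates the published scoring scheme exactly", {
  expect_identical(pefsScore(3, 0, 0), 6)      # three clean pairs
  expect_identical(pefsScore(5, 0, 1), 9.5)
  expect_identical(pefsScore(5, 0, 0), 10)
  expect_identical(pefsScore(3, 1, 0), 5)
  expect_equal(pefsScore(4, 2, 3), 2 * 4 - 2 - 0.5 * 3)
  expect_error(pefsScore(0, 0, 0), "P >= 1")
  expect_error(pefsScore(3, -1, 0), "non-negative")
  ## vectorized evaluation
  expect_identical(pefsScore(c(3, 5), c(0, 0), c(0, 1)), c(6, 9.5))
})

test_that("candidates recompute P, D, M from their supporting evidence", {
  ## duplicate = same (chrom, strand, start) as an earlier supporting read
  asg <- mkAssigned("GA", "GB", starts1 = c(100, 100, 300),
                    starts2 = c(900, 800, 700))
  cands <- buildCandidates(asg, fusionConfig())
  expect_length(cands, 1L)
  cand <- cands[[1]]
  expect_identical(supportCount(cand), 3L)
  expect_identical(duplicateCount(cand), 1L)   # second read at chr1:100
  expect_identical(mismatchCount(cand), 0L)
  expect_identical(pefs(cand), 5)              # 2*3 - 1
  expect_identical(computePEFS(cand), pefs(cand))

  ## mismatches feed M at half a point each
  asg2 <- mkAssigned("GA", "GB", starts1 = c(1, 50, 90, 130, 170),
                     starts2 = c(900, 850, 800, 750, 700),
                     mm1 = c(1L, 0L, 0L, 0L, 0L))
  cand2 <- buildCandidates(asg2, fusionConfig())[[1]]
  expect_identical(mismatchCount(cand2), 1L)
  expect_identical(pefs(cand2), 9.5)
})

test_that("duplicates never raise PEFS and clean pairs add exactly two points", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    asg <- mkAssigned("GA", "GB",
                      starts1 = sample(1000, n), starts2 = sample(1000, n),
                      mm1 = sample(0:2, n, replace = TRUE))
    base <- buildCandidates(asg, fusionConfig())[[1]]

    dupRow <- asg[sample(n, 1), ]
    dupRow$pairId <- "dup"
    withDup <- buildCandidates(rbind(asg, dupRow), fusionConfig())[[1]]
    expect_lte(pefs(withDup), pefs(base) + 0)   # +2 pair, but -2 duplicates

    clean <- asg[1, ]
    clean$pairId <- "new"
    clean$start1 <- 5000L; clean$start2 <- 6000L
    clean$mm1 <- 0L; clean$mm2 <- 0L
    withClean <- buildCandidates(rbind(asg, clean), fusionConfig())[[1]]
    expect_equal(pefs(withClean), pefs(base) + 2)
  }
})

test_that("prioritization requires both three pairs and PEFS of five", {
  mk <- function(g5, g3, n, mm1 = 0L) {
    buildCandidates(mkAssigned(g5, g3, starts1 = seq_len(n) * 10,
                               starts2 = seq_len(n) * 10 + 5000,
                               mm1 = mm1), fusionConfig())[[1]]
  }
  keep1 <- mk("GA", "GB", 3)                        # P=3, pefs 6
  drop1 <- mk("GC", "GD", 2)                        # P=2, pefs 4
  drop2 <- mk("GE", "GF", 4, mm1 = c(2L, 2L, 2L, 1L))  # P=4, pefs 4.5
  big <- mk("GG", "GH", 5)                          # P=5, pefs 10
  out <- prioritizeCandidates(list(keep1, drop1, drop2, big), fusionConfig())
  expect_identical(vapply(out, function(x) x@gene5, character(1)),
                   c("GG", "GA"))                   # pefs-descending order
})

test_that("mate orientation on transcripts decides the 5' and 3' partners", {
  ref <- toyRef()
  gA <- ref$genes[["GENEA"]]; gB <- ref$genes[["GENEB"]]
  txA <- transcriptSequence(gA, ref$genome)
  txB <- transcriptSequence(gB, ref$genome)
  ## fragment of a GENEA->GENEB fusion transcript: mate1 from GENEA forward,
  ## mate2 reverse-complemented from GENEB
  m1 <- subseq(txA, 10, 59)
  m2 <- reverseComplement(subseq(txB, 200, 249))
  reads1 <- DNAStringSet(c(p1 = as.character(m1)))
  reads2 <- DNAStringSet(c(p1 = as.character(m2)))
  disc <- mkPair("p1", "chrA", 10L, "chrB", 900L)
  disc$category <- "interchromosomal"
  asg <- assignPairsToGenes(disc, reads1, reads2, ref$genes, ref$genome,
                            fusionConfig())
  expect_identical(nrow(asg), 1L)
  expect_identical(asg$gene5, "GENEA")
  expect_identical(asg$gene3, "GENEB")

  ## swapped mate content gives the reciprocal orientation
  asgR <- assignPairsToGenes(disc, reads2, reads1, ref$genes, ref$genome,
                             fusionConfig())
  expect_identical(asgR$gene5, "GENEA")   # strand logic, not mate order
  expect_identical(asgR$gene3, "GENEB")

  ## genuine reciprocal-fusion fragment: mate1 from GENEB forward
  asgRec <- assignPairsToGenes(
    disc,
    DNAStringSet(c(p1 = as.character(subseq(txB, 10, 59)))),
    DNAStringSet(c(p1 = as.character(reverseComplement(subseq(txA, 150, 199))))),
    ref$genes, ref$genome, fusionConfig())
  expect_identical(asgRec$gene5, "GENEB")
  expect_identical(asgRec$gene3, "GENEA")

  ## both mates in one gene: not a fusion pair
  asgSame <- assignPairsToGenes(
    disc,
    DNAStringSet(c(p1 = as.character(subseq(txA, 10, 59)))),
    DNAStringSet(c(p1 = as.character(reverseComplement(subseq(txA, 150, 199))))),
    ref$genes, ref$genome, fusionConfig())
  expect_identical(nrow(asgSame), 0L)
})

test_that("junction-spanning reads pick the junction and expose isoforms", {
  ref <- toyRef()
  gA <- ref$genes[["GENEA"]]; gB <- ref$genes[["GENEB"]]
  esA <- exonSequences(gA, ref$genome); esB <- exonSequences(gB, ref$genome)
  mkSpan <- function(e5, e3, off) {
    left <- as.character(subseq(esA[[e5]], width(esA)[e5] - off + 1L,
                                width(esA)[e5]))
    right <- as.character(subseq(esB[[e3]], 1L, 50L - off))
    paste0(left, right)
  }
  pool <- DNAStringSet(c(
    s1 = mkSpan(2, 3, 25), s2 = mkSpan(2, 3, 20),
    s3 = as.character(reverseComplement(DNAString(mkSpan(2, 3, 30)))),
    iso = mkSpan(1, 3, 25),
    junk = randomDNAString(50, seed = 123)))
  asg <- mkAssigned("GENEA", "GENEB", starts1 = c(10, 60, 110),
                    starts2 = c(900, 850, 800))
  cand <- buildCandidates(asg, fusionConfig())[[1]]
  cand <- findSpanningReads(cand, pool, ref$genes, ref$genome, fusionConfig())
  expect_identical(predictedJunction(cand), c(2L, 3L))
  iso <- isoforms(cand)
  expect_identical(nrow(iso), 2L)
  expect_true(any(iso$exon5 == 1L & iso$exon3 == 3L))
  expect_identical(sort(spanningReads(cand)$readId),
                   c("iso", "s1", "s2", "s3"))

  ## zero spanning reads leave the candidate unconfirmed
  none <- findSpanningReads(buildCandidates(asg, fusionConfig())[[1]],
                            DNAStringSet(), ref$genes, ref$genome,
                            fusionConfig())
  expect_true(anyNA(predictedJunction(none)))
  expect_identical(nrow(isoforms(none)), 0L)
})

test_that("reading-frame calls follow CDS phase across the junction", {
  ## hand-laid CDS geometry: exon boundaries at known phase offsets.
  ## GENEP: exons 60/60; CDS tx 13..57 -> 45 coding bases before the
  ## exon1|2 boundary is 60 - 12 = 48; 48 %% 3 == 0.
  fix <- buildToyGenome(list(
    list(geneId = "GENEP", chrom = "c1", strand = "+",
         exonLens = c(60L, 60L), utr5 = 12L, utr3 = 12L),
    list(geneId = "GENEQ", chrom = "c2", strand = "+",
         exonLens = c(60L, 60L, 60L), utr5 = 12L, utr3 = 12L),
    list(geneId = "GENER", chrom = "c1", strand = "+",
         exonLens = c(61L, 60L), utr5 = 12L, utr3 = 11L),
    list(geneId = "UTR5P", chrom = "c2", strand = "+",
         exonLens = c(30L, 60L, 60L), utr5 = 40L, utr3 = 12L),
    list(geneId = "NOCDS", chrom = "c1", strand = "+",
         exonLens = c(50L, 50L))))

  mkCand <- function(g5, g3, e5, e3) {
    asg <- mkAssigned(g5, g3, starts1 = c(1, 40, 80), starts2 = c(900, 850, 800))
    cand <- buildCandidates(asg, fusionConfig())[[1]]
    cand@predictedJunction <- c(as.integer(e5), as.integer(e3))
    cand
  }

  ## donor after exon 1 of GENEP: 48 coding bases (phase 0); acceptor at
  ## exon 2 of GENEQ: 48 coding bases consumed (phase 0) -> in frame
  yes <- determineInFrame(mkCand("GENEP", "GENEQ", 1, 2), fix$genes)
  expect_identical(inFrame(yes), "Y")

  ## GENER's first exon is one base longer: phase shifts by one -> out
  no <- determineInFrame(mkCand("GENER", "GENEQ", 1, 2), fix$genes)
  expect_identical(inFrame(no), "N")

  ## donor inside the 5' UTR (UTR5P exon 1 is all UTR: 30 < 40)
  utr <- determineInFrame(mkCand("UTR5P", "GENEQ", 1, 2), fix$genes)
  expect_identical(inFrame(utr), "UTR-truncation")

  ## missing CDS annotation
  expect_warning(
    unk <- determineInFrame(mkCand("NOCDS", "GENEQ", 1, 2), fix$genes),
    "missing CDS")
  expect_identical(inFrame(unk), "unknown")

  expect_error(determineInFrame(buildCandidates(
    mkAssigned("GENEP", "GENEQ", 1, 900), fusionConfig())[[1]], fix$genes),
    "predicted junction")
})

test_that("an in-frame call corresponds to an intact translated fusion protein", {
  ## independent check by translation: fuse the coding sequences at the
  ## junction and verify the downstream peptide is preserved
  fix <- buildToyGenome(list(
    list(geneId = "GENEP", chrom = "c1", strand = "+",
         exonLens = c(60L, 60L), utr5 = 12L, utr3 = 12L),
    list(geneId = "GENEQ", chrom = "c2", strand = "+",
         exonLens = c(60L, 60L, 60L), utr5 = 12L, utr3 = 12L)))
  gP <- fix$genes[["GENEP"]]; gQ <- fix$genes[["GENEQ"]]
  txP <- transcriptSequence(gP, fix$genome)
  txQ <- transcriptSequence(gQ, fix$genome)
  fusionTx <- xscat(subseq(txP, 1, 60), subseq(txQ, 61, length(txQ)))
  ## CDS of the fusion starts at GENEP's start codon (tx position 13)
  fusCoding <- subseq(fusionTx, 13, length(fusionTx))
  fusCoding <- subseq(fusCoding, 1, 3 * (length(fusCoding) %/% 3))
  pep <- suppressWarnings(as.character(translate(fusCoding)))
  ## downstream peptide of wild-type GENEQ from the same phase position
  qCoding <- subseq(txQ, 61, length(txQ))   # exon 2 onward, phase 0
  qCoding <- subseq(qCoding, 1, 3 * (length(qCoding) %/% 3))
  qPep <- suppressWarnings(as.character(translate(qCoding)))
  qPart <- substr(pep, 17, 16 + nchar(qPep))   # after 48/3 = 16 codons
  expect_identical(qPart, qPep)
})

test_that("reciprocal fusions stay separate through candidate building", {
  asgF <- mkAssigned("GA", "GB", starts1 = c(1, 60, 120),
                     starts2 = c(900, 850, 800))
  asgR <- mkAssigned("GB", "GA", starts1 = c(5000, 5100, 5200),
                     starts2 = c(7000, 7100, 7200))
  cands <- buildCandidates(rbind(asgF, asgR), fusionConfig())
  expect_length(cands, 2L)
  expect_setequal(names(cands), c("GA->GB", "GB->GA"))
})
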