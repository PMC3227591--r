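test_that("3' trimming shortens every read by exactly n bases", {
  set.seed(42)
  reads <- dnaSet(vapply(1:5, function(i) randomDNAString(76), character(1)))
  trimmed <- trimReads(reads, 40)
  expect_true(all(width(trimmed) == 36L))
  expect_identical(as.character(trimmed[[1]]),
                   substr(as.character(reads[[1]]), 1, 36))
  expect_identical(trimReads(reads, 0), reads)
  short <- dnaSet(randomDNAString(36))
  expect_error(trimReads(short, 40), "read001")
})

test_that("end-to-end alignment flags unique, multi-mapped and unmapped reads", {
  set.seed(7)
  uniqSeg <- randomDNAString(50)
  dupSeg <- randomDNAString(50)
  chr1 <- DNAString(paste0(randomDNAString(200), uniqSeg, randomDNAString(150),
                           dupSeg, randomDNAString(100)))
  chr2 <- DNAString(paste0(randomDNAString(120), dupSeg, randomDNAString(180)))
  targets <- DNAStringSet(list(chr1 = chr1, chr2 = chr2))
  reads <- DNAStringSet(c(
    uniq = uniqSeg,
    multi = dupSeg,
    rc = as.character(reverseComplement(DNAString(uniqSeg))),
    none = randomDNAString(50)))
  aln <- alignEndToEnd(reads, targets)

  u <- aln[aln$readId == "uniq", ]
  expect_identical(nrow(u), 1L)
  expect_true(u$unique); expect_identical(u$mismatches, 0L)
  expect_identical(u$start, 201L)

  m <- aln[aln$readId == "multi", ]
  expect_identical(nrow(m), 2L)
  expect_true(all(!m$unique))

  r <- aln[aln$readId == "rc", ]
  expect_identical(r$strand, "-")
  expect_identical(r$start, 201L)

  expect_false("none" %in% aln$readId)
  expect_identical(names(unalignedReads(reads, aln)), "none")
})

test_that("mismatched reads get their best placements within the budget", {
  set.seed(8)
  seg <- randomDNAString(50)
  targets <- DNAStringSet(c(chr = paste0(randomDNAString(100), seg,
                                         randomDNAString(100))))
  mutate1 <- function(s, at, to) { substr(s, at, at) <- to; s }
  base <- strsplit(seg, "")[[1]]
  r1 <- mutate1(seg, 10, setdiff(c("A", "C", "G", "T"), base[10])[1])
  r3 <- r1
  for (at in c(20, 30)) r3 <- mutate1(r3, at, setdiff(c("A", "C", "G", "T"),
                                                      base[at])[1])
  reads <- DNAStringSet(c(one = r1, three = r3))
  aln <- alignEndToEnd(reads, targets, fusionConfig(maxMismatches = 2))
  expect_identical(aln$readId, "one")
  expect_identical(aln$mismatches, 1L)
  expect_identical(aln$start, 101L)      # three substitutions exceed the budget
})

test_that("splice-junction-spanning reads fail the genome but map to the library", {
  ref <- toyRef()
  g <- ref$genes[["GENEA"]]
  tx <- transcriptSequence(g, ref$genome)
  ends <- cumsum(width(exons(g)))
  ## read centred on the exon1/exon2 junction
  read <- subseq(tx, ends[1] - 24L, ends[1] + 25L)
  reads <- DNAStringSet(c(spliced = as.character(read)))
  gAln <- alignEndToEnd(reads, ref$genome)
  expect_identical(nrow(gAln), 0L)
  lib <- buildSpliceJunctionLibrary(ref$genes, ref$genome, x = 50)
  jAln <- alignEndToEnd(reads, junctionSeqs(lib))
  expect_identical(jAln$targetId, "GENEA|1|GENEA|2|50")
  expect_identical(jAln$mismatches, 0L)
})

test_that("local alignment scores match the Smith-Waterman oracle on seeded instances", {
  set.seed(20240915)
  cfg <- fusionConfig(minLocalScore = 16)
  nCases <- 60
  checked <- 0L
  for (case in seq_len(nCases)) {
    tlen <- sample(80:300, 1)
    rlen <- sample(20:60, 1)
    target <- randomDNAString(tlen)
    kind <- case %% 3L
    if (kind == 0L) {
      readChr <- randomDNAString(rlen)                     # unrelated read
    } else {
      s <- sample(tlen - rlen + 1L, 1)
      readChr <- substr(target, s, s + rlen - 1L)
      if (kind == 1L) {                                    # partial copy
        keep <- sample(10:rlen, 1)
        readChr <- paste0(substr(readChr, 1, keep),
                          randomDNAString(rlen - keep))
      }
    }
    reads <- DNAStringSet(c(r = readChr))
    targets <- DNAStringSet(c(t = target))
    hits <- localAlign(reads, targets, cfg)
    oracle <- max(swOracleScore(readChr, target),
                  swOracleScore(as.character(
                    reverseComplement(DNAString(readChr))), target))
    if (oracle >= cfg@minLocalScore) {
      expect_identical(nrow(hits), 1L)
      expect_equal(hits$score, oracle)
      checked <- checked + 1L
    } else {
      expect_identical(nrow(hits), 0L)
    }
  }
  expect_gt(checked, 15L)    # the suite must actually exercise scored hits
})

test_that("local alignment reports the aligned block in read coordinates", {
  set.seed(31)
  target <- randomDNAString(200)
  block <- substr(target, 51, 75)                  # 25 bp copy
  readChr <- paste0(block, randomDNAString(25))    # first 25 of 50 copy
  hits <- localAlign(DNAStringSet(c(r = readChr)), DNAStringSet(c(t = target)))
  expect_identical(hits$readStart, 1L)
  expect_identical(hits$readEnd, 25L)
  expect_identical(hits$targetStart, 51L)

  ## a fully matching read gives one full-length local alignment
  full <- localAlign(DNAStringSet(c(r = substr(target, 31, 80))),
                     DNAStringSet(c(t = target)))
  expect_identical(full$readStart, 1L)
  expect_identical(full$readEnd, 50L)
  expect_equal(full$score, 50)
})

test_that("exact short matching reports every placement and only exact ones", {
  set.seed(12)
  exonA <- randomDNAString(80)
  targets <- DNAStringSet(c(exonA = exonA,
                            polyA = strrep("A", 60)))
  frag <- substr(exonA, 1, 15)
  hits <- exactShortAlign(DNAStringSet(c(f = frag)), targets)
  fwd <- hits[hits$strand == "+", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$targetId, "exonA")
  expect_identical(fwd$start, 1L)
  ## brute-force oracle agrees
  expect_identical(fwd$start, bruteExactHits(frag, exonA))

  polyHits <- exactShortAlign(DNAStringSet(c(p = strrep("A", 15))), targets)
  expect_identical(sum(polyHits$targetId == "polyA" & polyHits$strand == "+"),
                   60L - 15L + 1L)

  mut <- frag
  substr(mut, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                               substr(frag, 8, 8))[1]
  mutHits <- exactShortAlign(DNAStringSet(c(m = mut)), targets)
  expect_false("exonA" %in% mutHits$targetId[mutHits$start == 1])

  expect_warning(
    short <- exactShortAlign(DNAStringSet(c(s = "ACGTA")), targets),
    "floor")
  expect_identical(nrow(short), 0L)
})

test_that("SAM import reproduces the built-in aligner's pair table", {
  spec <- simulationSpec(seed = 5, errorRate = 0, duplicateFraction = 0,
                         depth = 4,
                         fusions = fusionEvent("GENE001", 2, "GENE004", 3,
                                               multiplier = 1))
  ref <- generateReference(spec)
  fus <- injectFusion(ref, spec)
  sim <- simulateReads(spec, ref, fus)
  cfg <- fusionConfig()
  a1 <- alignEndToEnd(sim$reads$mate1, ref$genome, cfg)
  a2 <- alignEndToEnd(sim$reads$mate2, ref$genome, cfg)
  pairs <- pairAlignments(a1, a2)
  sam <- tempfile(fileext = ".sam")
  writeSAM(pairs, sim$reads$mate1, sim$reads$mate2, ref$genome, sam)
  imp <- importAlignments(sam, cfg)
  impPairs <- importedPairs(imp)
  o1 <- order(pairs$pairId); o2 <- order(impPairs$pairId)
  for (col in c("pairId", "chrom1", "start1", "strand1", "mm1",
                "chrom2", "start2", "strand2", "mm2"))
    expect_identical(as.vector(pairs[[col]][o1]),
                     as.vector(impPairs[[col]][o2]))

  ## identical downstream fusion calls from both routes
  resA <- detectFusionsPE(sim$reads$mate1, sim$reads$mate2, ref$genes,
                          ref$genome, cfg)
  resB <- detectFusionsPE(sim$reads$mate1, sim$reads$mate2, ref$genes,
                          ref$genome, cfg, pairs = impPairs)
  expect_identical(candidateTable(resA$candidates)[, c("gene5", "gene3", "P", "pefs")],
                   candidateTable(resB$candidates)[, c("gene5", "gene3", "P", "pefs")])
})

test_that("error-free reads from unique loci are all recovered at their origin", {
  spec <- simulationSpec(seed = 21, errorRate = 0, duplicateFraction = 0,
                         readMode = "se", depth = 3, nGenes = 4)
  ref <- generateReference(spec)
  sim <- simulateReads(spec, ref)
  aln <- alignEndToEnd(sim$reads, ref$genome, fusionConfig())
  aln <- aln[aln$unique, ]
  prov <- sim$provenance
  ## reads fully inside one exon must map, uniquely, to the right chromosome
  models <- as.list(ref$genes)
  insideExon <- vapply(seq_len(nrow(prov)), function(i) {
    g <- models[[prov$source[i]]]
    ends <- cumsum(width(exons(g)))
    starts <- c(1L, head(ends, -1L) + 1L)
    any(prov$start[i] >= starts & (prov$start[i] + 49L) <= ends)
  }, logical(1))
  ids <- prov$readId[insideExon]
  expect_true(all(ids %in% aln$readId))
  chromOf <- vapply(models, chrom, character(1))
  hit <- aln[match(ids, aln$readId), ]
  expect_identical(as.vector(hit$targetId),
                   unname(chromOf[prov$source[insideExon]]))
})
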