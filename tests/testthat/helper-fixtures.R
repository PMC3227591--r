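## shared fixtures built in code: a hand-laid toy genome whose gene structures
## and sequences are fully known to the tests

suppressPackageStartupMessages({
  library(Biostrings)
  library(IRanges)
  library(S4Vectors)
})

randomDNAString <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Lay out genes with explicit exon lengths on fresh chromosomes.
## geneSpecs: list of list(geneId, chrom, strand, exonLens, utr5, utr3)
## Returns list(genome, genes) with intron/intergenic spacers of `gap` bp.
buildToyGenome <- function(geneSpecs, gap = 200L, seed = 99L) {
  set.seed(seed)
  chroms <- unique(vapply(geneSpecs, `[[`, character(1), "chrom"))
  cursor <- setNames(rep(0L, length(chroms)), chroms)
  pieces <- setNames(vector("list", length(chroms)), chroms)
  models <- list()
  for (gs in geneSpecs) {
    ch <- gs$chrom
    exLens <- as.integer(gs$exonLens)
    starts <- integer(length(exLens))
    for (k in seq_along(exLens)) {
      pieces[[ch]] <- c(pieces[[ch]], randomDNAString(gap),
                        randomDNAString(exLens[k]))
      starts[k] <- cursor[ch] + gap + 1L
      cursor[ch] <- cursor[ch] + gap + exLens[k]
    }
    ends <- starts + exLens - 1L
    gm <- geneModel(gs$geneId, ch, gs$strand, IRanges(starts, ends))
    if (!is.null(gs$utr5)) {
      L <- sum(exLens)
      cdsLen <- L - gs$utr5 - gs$utr3
      g1 <- fusionfindR:::.txToGenomic(gm, gs$utr5 + 1L)
      g2 <- fusionfindR:::.txToGenomic(gm, gs$utr5 + cdsLen)
      gm <- geneModel(gs$geneId, ch, gs$strand, exons(gm),
                      cds = range(c(g1, g2)))
    }
    models[[length(models) + 1L]] <- gm
  }
  for (ch in chroms)
    pieces[[ch]] <- c(pieces[[ch]], randomDNAString(gap))
  genome <- DNAStringSet(vapply(pieces, paste, character(1), collapse = ""))
  names(genome) <- chroms
  list(genome = genome, genes = GeneModelList(models))
}

## default two-gene fixture used across alignment/SE/PE unit tests
toyRef <- function(seed = 99L) {
  buildToyGenome(list(
    list(geneId = "GENEA", chrom = "chrA", strand = "+",
         exonLens = c(100L, 120L, 90L), utr5 = 20L, utr3 = 25L),
    list(geneId = "GENEB", chrom = "chrB", strand = "-",
         exonLens = c(80L, 150L, 110L, 100L), utr5 = 15L, utr3 = 30L)),
    seed = seed)
}

dnaSet <- function(...) {
  x <- DNAStringSet(c(...))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- sprintf("read%03d", seq_along(x))
  x
}
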