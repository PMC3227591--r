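## independent Smith-Waterman oracle: naive dynamic programming with linear
## gap costs (match +1, mismatch -1, gap -2 per base), returning the best
## local-alignment score.  Deliberately simple and separate from the package's
## alignment code path.
swOracleScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(as.character(a), "")[[1]]
  b <- strsplit(as.character(b), "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s, H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
      if (H[i + 1L, j + 1L] > best) best <- H[i + 1L, j + 1L]
    }
  }
  best
}

## brute-force substring search (both orientations handled by caller)
bruteExactHits <- function(fragment, target) {
  frag <- as.character(fragment); targ <- as.character(target)
  w <- nchar(frag)
  hits <- integer()
  for (s in seq_len(nchar(targ) - w + 1L)) {
    if (substr(targ, s, s + w - 1L) == frag) hits <- c(hits, s)
  }
  hits
}
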