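# Independent oracles used by the tests. These deliberately avoid the package's
# own code paths (Biostrings matching, rle-based run merging) so that agreement
# is informative.

# Semi-global edit distance: `pattern` must align end-to-end against some
# substring of `text` (free text ends); full dynamic programme, O(|p| |t|),
# vectorised over the pattern dimension.
semiGlobalEditDist <- function(pattern, text) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tt <- strsplit(text, "", fixed = TRUE)[[1]]
  m <- length(p)
  if (length(tt) == 0L) return(m)
  prev <- 0:m          # D[i][j-1], i = 0..m; D[i][0] = i
  best <- m
  idx <- seq_len(m)
  for (j in seq_along(tt)) {
    # diagonal (substitution/match) and text-gap (insertion) moves
    base <- pmin(prev[idx] + (p != tt[j]), prev[idx + 1L] + 1)
    # pattern-gap chains: cur[i] = min(base[i], cur[i-1] + 1) with cur[0] = 0,
    # closed form cur[i] = i + min(0, min_{k<=i}(base[k] - k))
    cur <- idx + pmin(0, cummin(base - idx))
    prev <- c(0, cur)
    best <- min(best, cur[m])
  }
  best
}

# oracle hit decision matching the scanReads contract (both strands optional)
oracleHit <- function(junction, read, maxEdits, bothStrands = TRUE) {
  d <- semiGlobalEditDist(junction, read)
  if (bothStrands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(junction)))
    d <- min(d, semiGlobalEditDist(rc, read))
  }
  d <= maxEdits
}

# Brute-force segment caller: per-bin walk (no rle), mirroring the published
# contract: maximal qualifying runs, gap merging, minimum length.
bruteForceCalls <- function(ratios, binStarts, binEnds, threshold, direction,
                            maxGapBins, minLen) {
  qual <- if (direction == "up") ratios >= threshold else ratios <= threshold
  n <- length(qual)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (qual[i]) {
      j <- i
      while (j < n && qual[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(NULL)
  merged <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- merged[[length(merged)]]
    if (r[1L] - last[2L] - 1L <= maxGapBins)
      merged[[length(merged)]] <- c(last[1L], r[2L])
    else merged[[length(merged) + 1L]] <- r
  }
  out <- do.call(rbind, lapply(merged, function(r) {
    s <- binStarts[r[1L]]; e <- binEnds[r[2L]]
    if (e - s + 1L < minLen) return(NULL)
    c(start = s, end = e)
  }))
  out
}

# brute-force exact substring presence (both strands), character-level
bruteForceOccurs <- function(needle, haystack) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(needle)))
  grepl(needle, haystack, fixed = TRUE) || grepl(rc, haystack, fixed = TRUE)
}

# default two-duplication simulation scenario used across tests: a scaled-down
# chromosome with a two-segment circular element
makeTestScenario <- function(seed, genomeLength = 60000L,
                             dup1 = c(10001L, 22000L),
                             dup2 = c(28001L, 39000L), gc = 0.45) {
  g <- generateGenome(genomeLength, gc, seed = seed)
  sc <- buildScenario(g, dup1, dup2)
  sc$genome <- g
  sc
}

# read sources for a scenario: chromosome (weight 1) + circle at `weight`
scenarioSources <- function(sc, weight) {
  list(chr = list(seq = sc$genome[[1]], circular = FALSE, weight = 1),
       circle = list(seq = circleSequence(sc$circle), circular = TRUE,
                     weight = weight))
}

errorFreeParams <- function(totalBases, meanLog = log(3000), sdLog = 0.35) {
  readSimParams(totalBases = totalBases, meanLog = meanLog, sdLog = sdLog,
                subRate = 0, insRate = 0, delRate = 0)
}
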