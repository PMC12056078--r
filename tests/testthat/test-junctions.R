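test_that("junctions are built from the oriented segment flanks", {
  sc <- makeTestScenario(seed = 61, genomeLength = 20000L,
                         dup1 = c(2001L, 7000L), dup2 = c(9001L, 11000L))
  g <- sc$genome[[1]]
  jn <- buildJunctions(sc$layout, g, flankK = 25)
  expect_identical(length(jn), 2L)
  expect_true(all(Biostrings::width(jn) == 50L))
  expect_identical(
    as.character(jn[["dup1+|dup2+"]]),
    paste0(as.character(Biostrings::subseq(g, 6976, 7000)),
           as.character(Biostrings::subseq(g, 9001, 9025))))
  expect_identical(
    as.character(jn[["dup2+|dup1+"]]),
    paste0(as.character(Biostrings::subseq(g, 10976, 11000)),
           as.character(Biostrings::subseq(g, 2001, 2025))))

  # single-segment circle: last k + first k of the same segment
  one <- GenomicRanges::GRanges("chr", IRanges::IRanges(101, 400), strand = "+")
  names(one) <- "seg"
  j1 <- buildJunctions(CircleLayout(one), g, flankK = 25)
  expect_identical(length(j1), 1L)
  expect_identical(as.character(j1[[1]]),
                   paste0(as.character(Biostrings::subseq(g, 376, 400)),
                          as.character(Biostrings::subseq(g, 101, 125))))

  short <- GenomicRanges::GRanges("chr", IRanges::IRanges(101, 110), strand = "+")
  names(short) <- "seg"
  expect_error(buildJunctions(CircleLayout(short), g, flankK = 25),
               class = "invalid_parameter")
})

test_that("specificity checking finds genomic copies on either strand", {
  g <- generateGenome(30000, 0.5, seed = 62)
  # a 50-mer lifted verbatim from the reference is not specific
  taken <- Biostrings::DNAStringSet(as.character(
    Biostrings::subseq(g[[1]], 12001, 12050)))
  names(taken) <- "lifted"
  js <- new("JunctionSet", taken, flankK = 25L)
  res <- checkSpecificity(js, g)
  expect_false(res$specific[1])
  expect_true(12001 %in% res$positions[[1]])

  # ... nor is its reverse complement
  rc <- Biostrings::reverseComplement(taken)
  names(rc) <- "lifted_rc"
  expect_false(checkSpecificity(new("JunctionSet", rc, flankK = 25L), g)$specific[1])

  # truth junctions of a scenario are absent by construction (brute force)
  sc <- makeTestScenario(seed = 63)
  spec <- checkSpecificity(sc$junctions, sc$genome)
  expect_true(all(spec$specific))
  gchr <- as.character(sc$genome[[1]])
  for (j in as.character(sc$junctions))
    expect_false(bruteForceOccurs(j, gchr))
})

test_that("read scanning counts reads, normalises per Gb, and flags empties", {
  sc <- makeTestScenario(seed = 64)
  # arithmetic: counts / (bases / 1e9)
  rd <- simulateLongReads(scenarioSources(sc, 5),
                          errorFreeParams(4e5, meanLog = log(2500)), seed = 65)
  rep <- scanReads(rd, sc$junctions)
  expect_equal(rep$table$readsPerGb,
               rep$table$readCount / (rep$totalBases / 1e9))
  expect_true(all(rep$table$readCount >= 1))
  circleReads <- names(rd)[S4Vectors::mcols(rd)$source == "circle"]
  expect_true(all(unlist(rep$hitIds) %in% circleReads))

  # chromosome-only reads carry no circle junction
  rd0 <- simulateLongReads(scenarioSources(sc, 0),
                           errorFreeParams(4e5, meanLog = log(2500)), seed = 66)
  rep0 <- scanReads(rd0, sc$junctions)
  expect_identical(rep0$table$readCount, c(0L, 0L))
  expect_identical(unname(callPresence(rep0)), c(FALSE, FALSE))

  # empty read set: flagged, NA rate, no crash
  empty <- scanReads(Biostrings::DNAStringSet(), sc$junctions)
  expect_true(empty$empty)
  expect_identical(empty$totalBases, 0)
  expect_true(all(is.na(empty$table$readsPerGb)))
})

test_that("edit-distance scanning matches a full DP oracle and is monotone", {
  withr::with_seed(67, {
    bases <- c("A", "C", "G", "T")
    jn <- paste(sample(bases, 50, TRUE), collapse = "")
    jset <- Biostrings::DNAStringSet(jn); names(jset) <- "J"
    js <- new("JunctionSet", jset, flankK = 25L)

    # a read with exactly 2 substitutions inside the junction window
    v <- strsplit(jn, "")[[1]]
    for (pos in c(10, 30))
      v[pos] <- setdiff(bases, v[pos])[1]
    read2 <- Biostrings::DNAStringSet(paste0(
      paste(sample(bases, 40, TRUE), collapse = ""),
      paste(v, collapse = ""),
      paste(sample(bases, 40, TRUE), collapse = "")))
    names(read2) <- "r"
    expect_identical(scanReads(read2, js, matchParams(0))$table$readCount, 0L)
    expect_identical(scanReads(read2, js, matchParams(3))$table$readCount, 1L)

    # agreement with the DP oracle on random pairs, mixed mutated/unrelated
    mutate <- function(s, nEdits) {
      v <- strsplit(s, "")[[1]]
      for (e in seq_len(nEdits)) {
        op <- sample(3, 1); pos <- sample(length(v), 1)
        if (op == 1) v[pos] <- sample(bases, 1)
        else if (op == 2) v[pos] <- ""
        else v[pos] <- paste0(v[pos], sample(bases, 1))
      }
      paste(v, collapse = "")
    }
    for (i in 1:200) {
      j <- paste(sample(bases, 50, TRUE), collapse = "")
      read <- paste(sample(bases, 120, TRUE), collapse = "")
      if (runif(1) < 0.7) {
        emb <- mutate(j, sample(0:5, 1))
        if (runif(1) < 0.5)
          emb <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(emb)))
        at <- sample(1:(120 - nchar(emb)), 1)
        read <- paste0(substr(read, 1, at - 1), emb,
                       substr(read, at + nchar(emb), 120))
      }
      k <- sample(0:3, 1)
      jj <- Biostrings::DNAStringSet(j); names(jj) <- "J"
      got <- scanReads(Biostrings::DNAStringSet(c(r = read)),
                       new("JunctionSet", jj, flankK = 25L),
                       matchParams(k))$table$readCount == 1L
      expect_identical(got, oracleHit(j, read, k))
    }

    # monotonicity: counts never decrease as maxEdits grows
    sc <- makeTestScenario(seed = 68)
    rd <- simulateLongReads(scenarioSources(sc, 2),
                            readSimParams(totalBases = 3e5,
                                          meanLog = log(2500), sdLog = 0.3,
                                          subRate = 0.02, insRate = 0.01,
                                          delRate = 0.02), seed = 69)
    prev <- c(0L, 0L)
    for (k in 0:3) {
      cnt <- scanReads(rd, sc$junctions, matchParams(k))$table$readCount
      expect_true(all(cnt >= prev))
      prev <- cnt
    }
  })
})

test_that("hit counts are strand symmetric and normalisation scales inversely", {
  sc <- makeTestScenario(seed = 71)
  rd <- simulateLongReads(scenarioSources(sc, 3),
                          errorFreeParams(4e5, meanLog = log(2500)), seed = 72)
  rep <- scanReads(rd, sc$junctions, matchParams(0, scanBothStrands = TRUE))
  rc <- Biostrings::reverseComplement(rd)
  names(rc) <- names(rd)
  repRC <- scanReads(rc, sc$junctions, matchParams(0, scanBothStrands = TRUE))
  expect_identical(rep$table$readCount, repRC$table$readCount)

  # duplicating the non-hit content halves nothing in counts but dilutes rates
  hit <- unique(unlist(rep$hitIds))
  nonhit <- rd[setdiff(names(rd), hit)]
  diluted <- c(rd, nonhit)
  rep2 <- scanReads(diluted, sc$junctions)
  expect_identical(rep2$table$readCount, rep$table$readCount)
  expect_equal(rep2$table$readsPerGb,
               rep$table$readsPerGb * rep$totalBases /
                 (rep$totalBases + sum(as.numeric(Biostrings::width(nonhit)))))
})

test_that("junction abundance separates circle-bearing from circle-free conditions", {
  sc <- makeTestScenario(seed = 73)
  rpgCO <- rpgGlc <- numeric(5)
  for (s in 1:5) {
    rdCO <- simulateLongReads(scenarioSources(sc, 2),
                              errorFreeParams(3e5, meanLog = log(2500)),
                              seed = 800 + s)
    rdGlc <- simulateLongReads(scenarioSources(sc, 0),
                               errorFreeParams(3e5, meanLog = log(2500)),
                               seed = 850 + s)
    rpgCO[s] <- mean(scanReads(rdCO, sc$junctions)$table$readsPerGb)
    rpgGlc[s] <- mean(scanReads(rdGlc, sc$junctions)$table$readsPerGb)
  }
  expect_true(all(rpgGlc == 0))   # exact zero at maxEdits = 0
  expect_gt(mean(rpgCO), 0)
  pres <- callPresence(scanReads(
    simulateLongReads(scenarioSources(sc, 2),
                      errorFreeParams(3e5, meanLog = log(2500)), seed = 871),
    sc$junctions))
  expect_true(all(pres))
})

test_that("junction sets round-trip through FASTA and JSON", {
  sc <- makeTestScenario(seed = 74, genomeLength = 20000L,
                         dup1 = c(2001L, 7000L), dup2 = c(9001L, 11000L))
  fa <- tempfile(fileext = ".fa"); js <- tempfile(fileext = ".json")
  writeJunctions(sc$junctions, fa)
  writeJunctions(sc$junctions, js)
  expect_identical(as.character(readJunctions(fa)), as.character(sc$junctions))
  expect_identical(as.character(readJunctions(js)), as.character(sc$junctions))
  expect_identical(flankK(readJunctions(js)), 25L)
})
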