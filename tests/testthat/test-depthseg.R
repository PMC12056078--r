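test_that("bin normalisation divides by the genome-median bin depth", {
  dt <- DepthTrack(rep(100, 20000))
  bins <- binAndNormalize(dt, 1000)
  expect_true(all(bins$ratio == 1))

  # 802x background with a 1765x event: event-bin ratio ~= 2.201
  dt2 <- DepthTrack(rep(c(802, 1765, 802), c(20000, 10000, 20000)))
  bins2 <- binAndNormalize(dt2, 1000)
  ev <- bins2$ratio[GenomicRanges::start(bins2) >= 20001 &
                      GenomicRanges::end(bins2) <= 30000]
  expect_equal(unique(ev), 1765 / 802, tolerance = 1e-12)
  expect_equal(median(bins2$ratio), 1, tolerance = 1e-12)

  # shorter than one bin: a single bin with ratio 1
  small <- binAndNormalize(DepthTrack(rep(7, 120)), 1000)
  expect_identical(length(small), 1L)
  expect_equal(small$ratio, 1)

  expect_error(binAndNormalize(DepthTrack(rep(0, 5000)), 1000),
               class = "degenerate_input")
})

test_that("segment calling finds maximal runs, merges small gaps, drops short calls", {
  flat <- binAndNormalize(DepthTrack(rep(100, 50000)), 1000)
  expect_identical(length(callSegments(flat, segmentationParams())), 0L)

  # truth duplication [20001, 60000] at ratio 2.2 over depth 100
  ev <- GenomicRanges::GRanges("chr", IRanges::IRanges(20001, 60000),
                               copyRatio = 2.2)
  dt <- simulateDepthTrack(100000, ev, meanDepth = 100, seed = 31)
  calls <- callSegments(binAndNormalize(dt, 1000), segmentationParams())
  expect_identical(length(calls), 1L)
  expect_identical(as.character(calls$kind), "duplication")
  expect_lte(abs(GenomicRanges::start(calls) - 20001), 1000)
  expect_lte(abs(GenomicRanges::end(calls) - 60000), 1000)

  # two events separated by > maxGapBins stay two calls; a small gap merges
  r <- rep(1, 100); r[c(11:30, 41:60)] <- 2.2   # 10-bin gap
  mk <- function(ratios) {
    g <- GenomicRanges::GRanges("chr",
      IRanges::IRanges(seq(1, by = 1000, length.out = length(ratios)),
                       width = 1000),
      meanDepth = ratios * 100, ratio = ratios)
    S4Vectors::metadata(g) <- list(medianBinDepth = 100, binSize = 1000)
    g
  }
  expect_identical(length(callSegments(mk(r), segmentationParams())), 2L)
  r2 <- rep(1, 100); r2[c(11:30, 34:60)] <- 2.2  # 3-bin gap <= maxGapBins
  expect_identical(length(callSegments(mk(r2), segmentationParams())), 1L)
})

test_that("calls agree with a brute-force scan over maximal qualifying runs", {
  withr::with_seed(77, {
    for (case in 1:15) {
      nb <- sample(30:100, 1)
      ratios <- pmax(0, 1 + rnorm(nb, sd = 0.1))
      ndup <- sample(0:2, 1)
      for (d in seq_len(ndup)) {
        s <- sample(nb - 5, 1); e <- min(nb, s + sample(3:25, 1))
        ratios[s:e] <- 2.2 + rnorm(e - s + 1, sd = 0.1)
      }
      if (runif(1) < 0.5) {
        s <- sample(nb - 3, 1); e <- min(nb, s + sample(1:4, 1))
        ratios[s:e] <- abs(rnorm(e - s + 1, sd = 0.05))
      }
      bins <- GenomicRanges::GRanges("chr",
        IRanges::IRanges(seq(1, by = 1000, length.out = nb), width = 1000),
        meanDepth = ratios * 50, ratio = ratios)
      S4Vectors::metadata(bins) <- list(medianBinDepth = 50, binSize = 1000)
      p <- segmentationParams(maxGapBins = sample(0:5, 1),
                              minDupLength = 3000, minDelLength = 2000)
      calls <- callSegments(bins, p)
      oracle <- rbind(
        bruteForceCalls(ratios, GenomicRanges::start(bins),
                        GenomicRanges::end(bins), p$dupThreshold, "up",
                        p$maxGapBins, p$minDupLength),
        bruteForceCalls(ratios, GenomicRanges::start(bins),
                        GenomicRanges::end(bins), p$delThreshold, "down",
                        p$maxGapBins, p$minDelLength))
      if (is.null(oracle)) {
        expect_identical(length(calls), 0L)
      } else {
        oracle <- oracle[order(oracle[, "start"]), , drop = FALSE]
        expect_identical(GenomicRanges::start(calls),
                         unname(oracle[, "start"]))
        expect_identical(GenomicRanges::end(calls), unname(oracle[, "end"]))
      }
    }
  })
})

test_that("truth segments are recovered within one bin across seeds", {
  hits <- 0L
  nseed <- 50L
  for (s in seq_len(nseed)) {
    ev <- GenomicRanges::GRanges("chr", IRanges::IRanges(15001, 38000),
                                 copyRatio = 2.2)   # 23 bins
    dt <- simulateDepthTrack(60000, ev, meanDepth = 100, seed = 500 + s)
    calls <- callSegments(binAndNormalize(dt, 1000), segmentationParams())
    ok <- length(calls) == 1L &&
      abs(GenomicRanges::start(calls) - 15001) <= 1000 &&
      abs(GenomicRanges::end(calls) - 38000) <= 1000
    hits <- hits + ok
  }
  expect_gte(hits / nseed, 0.95)
})

test_that("boundary refinement lands on the depth step", {
  # noiseless step 100 -> 220 at base 50001
  d <- rep(c(100, 220), c(50000, 30000))
  dt <- DepthTrack(d)
  call <- GenomicRanges::GRanges("chr", IRanges::IRanges(50400, 79000),
                                 kind = "duplication")
  ref <- suppressWarnings(refineBoundaries(call, dt, 2000))  # end abuts track
  expect_identical(GenomicRanges::start(ref), 50001L)

  # Poisson noise at the published depth scale: within +/- 25 bp, 95% of seeds
  hits <- 0L
  for (s in 1:50) {
    ev <- GenomicRanges::GRanges("chr", IRanges::IRanges(5001, 12000),
                                 copyRatio = 1765 / 802)
    dtn <- simulateDepthTrack(16000, ev, meanDepth = 802, seed = 900 + s)
    cl <- GenomicRanges::GRanges("chr", IRanges::IRanges(5400, 11600))
    rf <- refineBoundaries(cl, dtn, 2000)
    ok <- abs(GenomicRanges::start(rf) - 5001) <= 25 &&
      abs(GenomicRanges::end(rf) - 12000) <= 25
    hits <- hits + ok
  }
  expect_gte(hits / 50, 0.95)

  # step at the very edge of the track: clamped, no crash
  edge <- GenomicRanges::GRanges("chr", IRanges::IRanges(300, 79000))
  expect_warning(refineBoundaries(edge, dt, 2000), "clamped")
})

test_that("copy-ratio estimates use the in-segment median", {
  bins <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(c(1, 1001, 2001), width = 1000),
    meanDepth = c(210, 220, 230), ratio = c(2.1, 2.2, 2.3))
  S4Vectors::metadata(bins) <- list(medianBinDepth = 100, binSize = 1000)
  call <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 3000))
  expect_identical(estimateCopyRatio(call, bins), 2.2)

  # simulated published-scale scenario: estimate in [2.0, 2.4]
  ev <- GenomicRanges::GRanges("chr", IRanges::IRanges(20001, 60000),
                               copyRatio = 1765 / 802)
  dt <- simulateDepthTrack(100000, ev, meanDepth = 802, seed = 41)
  bn <- binAndNormalize(dt, 1000)
  calls <- callSegments(bn, segmentationParams())
  est <- estimateCopyRatio(calls[1], bn)
  expect_gte(est, 2.0); expect_lte(est, 2.4)
})

test_that("segmentation is invariant to rescaling the whole track", {
  ev <- GenomicRanges::GRanges("chr", IRanges::IRanges(20001, 45000),
                               copyRatio = 2.2)
  dt <- simulateDepthTrack(80000, ev, meanDepth = 100, seed = 51)
  d <- as.numeric(depthValues(dt))
  for (cc in c(0.5, 3, 17.3)) {
    b1 <- binAndNormalize(dt, 1000)
    b2 <- binAndNormalize(DepthTrack(d * cc), 1000)
    expect_equal(b1$ratio, b2$ratio, tolerance = 1e-12)
    c1 <- callSegments(b1, segmentationParams())
    c2 <- callSegments(b2, segmentationParams())
    expect_identical(GenomicRanges::start(c1), GenomicRanges::start(c2))
    expect_identical(c1$copyRatio, c2$copyRatio)
  }
})

test_that("reports carry both the inclusive length and the end-start span", {
  calls <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(c(1839957, 1908405), c(1900058, 1934113)),
    kind = "duplication", copyRatio = c(2.2, 2.17))
  rep <- segmentReport(calls)
  expect_identical(rep$inclusiveLength, c(60102L, 25709L))
  expect_identical(rep$span, c(60101L, 25708L))
})

test_that("depth tracks round-trip through bedGraph and TSV", {
  d <- rep(c(0, 5, 3, 0), c(10, 25, 40, 5))
  dt <- DepthTrack(d, contig = "tig1")
  bg <- tempfile(fileext = ".bedGraph"); tsv <- tempfile(fileext = ".tsv")
  writeDepthTrack(dt, bg, "bedGraph")
  writeDepthTrack(dt, tsv, "tsv")
  expect_equal(as.numeric(depthValues(readDepthTrack(bg))), d)
  expect_equal(as.numeric(depthValues(readDepthTrack(tsv))), d)
  expect_identical(contigName(readDepthTrack(bg)), "tig1")
})
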