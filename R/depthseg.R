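# Copy-number segmentation of a depth track: median-normalised binning,
# thresholding with gap merging, base-level boundary refinement, and copy-ratio
# estimation.

#' Segmentation parameters
#'
#' Tuning knobs for [callSegments()] and [refineBoundaries()]. The duplication
#' threshold 1.75 sits between single copy (ratio 1) and the ~2.2 signal of a
#' chromosome plus one extrachromosomal copy; the deletion threshold 0.25
#' catches homozygous deletions (expected ratio ~0). Minimum lengths separate
#' megabase-scale duplications (>= 10 kb) from kb-scale deletions (>= 1 kb).
#'
#' @param binSize bin width in bases (>= 50; default 1000).
#' @param dupThreshold bin ratio at or above which a bin is duplication-like
#'   (> 1; default 1.75).
#' @param delThreshold bin ratio at or below which a bin is deletion-like
#'   (< 1; default 0.25).
#' @param minDupLength,minDelLength minimum called event length in bases
#'   (defaults 10000 and 1000).
#' @param maxGapBins qualifying runs separated by at most this many
#'   non-qualifying bins are merged (default 5).
#' @param refineWindow half-width in bases of the boundary search in
#'   [refineBoundaries()] (default 2000); the contrast window is half of it.
#' @return A validated named list.
#' @export
segmentationParams <- function(binSize = 1000L, dupThreshold = 1.75,
                               delThreshold = 0.25, minDupLength = 10000L,
                               minDelLength = 1000L, maxGapBins = 5L,
                               refineWindow = 2000L) {
  p <- list(binSize = as.integer(binSize), dupThreshold = dupThreshold,
            delThreshold = delThreshold, minDupLength = as.integer(minDupLength),
            minDelLength = as.integer(minDelLength),
            maxGapBins = as.integer(maxGapBins),
            refineWindow = as.integer(refineWindow))
  if (p$binSize < 50L)
    mtxStop("invalid_parameter", "binSize must be >= 50")
  if (!(p$delThreshold > 0 && p$delThreshold < 1 && p$dupThreshold > 1))
    mtxStop("invalid_parameter", "need 0 < delThreshold < 1 < dupThreshold")
  if (p$maxGapBins < 0L || p$minDupLength < 1L || p$minDelLength < 1L)
    mtxStop("invalid_parameter", "lengths must be positive and maxGapBins >= 0")
  p
}

#' Bin a depth track and normalise by the genome-median bin depth
#'
#' Per-bin mean depths are divided by the genome-wide *median* of bin means, so
#' that even a duplication spanning several percent of the genome cannot drag
#' the baseline; the output ratio track has median 1 (up to one bin's
#' quantisation). The final partial bin, if any, is kept.
#'
#' @param track a [DepthTrack-class].
#' @param binSize bin width in bases.
#' @return A [GenomicRanges::GRanges] of bins with metadata columns `meanDepth`
#'   and `ratio`; `metadata()` carries `medianBinDepth` and `binSize`.
#' @examples
#' dt <- DepthTrack(rep(c(802, 1765, 802), c(20000, 10000, 20000)))
#' bins <- binAndNormalize(dt, 1000)
#' range(bins$ratio)
#' @export
binAndNormalize <- function(track, binSize = 1000L) {
  stopifnot(is(track, "DepthTrack"))
  d <- depthValues(track)
  L <- length(d)
  binSize <- as.integer(binSize)
  starts <- seq.int(1L, L, by = binSize)
  ends <- pmin(starts + binSize - 1L, L)
  mu <- viewMeans(Views(d, start = starts, end = ends))
  med <- median(mu)
  if (med == 0)
    mtxStop("degenerate_input", "median bin depth is zero; cannot normalise")
  gr <- GRanges(contigName(track), IRanges(starts, ends),
                meanDepth = as.numeric(mu), ratio = as.numeric(mu) / med)
  metadata(gr) <- list(medianBinDepth = med, binSize = binSize,
                       trackLength = L)
  gr
}

# maximal runs of `qual` (logical), merging runs separated by <= maxGap FALSE
# bins; returns a two-column matrix of first/last bin indices
.mergeRuns <- function(qual, maxGap) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) <= 1L) return(runs)
  keep <- runs[1L, , drop = FALSE]
  for (i in 2L:nrow(runs)) {
    gap <- runs[i, 1L] - keep[nrow(keep), 2L] - 1L
    if (gap <= maxGap) {
      keep[nrow(keep), 2L] <- runs[i, 2L]
    } else {
      keep <- rbind(keep, runs[i, , drop = FALSE])
    }
  }
  keep
}

#' Call duplicated and deleted segments from a normalised bin track
#'
#' Duplications are maximal runs of bins with `ratio >= dupThreshold`,
#' deletions maximal runs with `ratio <= delThreshold`; runs separated by at
#' most `maxGapBins` non-qualifying bins are merged, and calls shorter than the
#' kind-specific minimum length are discarded. Calls are sorted by start and
#' never overlap.
#'
#' @param bins output of [binAndNormalize()].
#' @param params a [segmentationParams()] list.
#' @return A [GenomicRanges::GRanges] of calls with metadata columns `kind`
#'   (`"duplication"`/`"deletion"`), `copyRatio` (median in-call bin ratio, 2
#'   decimals), `meanDepthInside`, and `genomeMedianDepth`. Empty GRanges when
#'   nothing qualifies.
#' @examples
#' dt <- DepthTrack(rep(c(100, 220, 100), c(30000, 15000, 30000)))
#' callSegments(binAndNormalize(dt, 1000), segmentationParams())
#' @export
callSegments <- function(bins, params = segmentationParams()) {
  med <- metadata(bins)$medianBinDepth
  out <- list()
  for (kind in c("duplication", "deletion")) {
    qual <- if (kind == "duplication") bins$ratio >= params$dupThreshold
            else bins$ratio <= params$delThreshold
    if (!any(qual)) next
    runs <- .mergeRuns(qual, params$maxGapBins)
    minLen <- if (kind == "duplication") params$minDupLength else params$minDelLength
    for (i in seq_len(nrow(runs))) {
      s <- start(bins)[runs[i, 1L]]
      e <- end(bins)[runs[i, 2L]]
      if (e - s + 1L < minLen) next
      inRatio <- bins$ratio[runs[i, 1L]:runs[i, 2L]]
      inDepth <- bins$meanDepth[runs[i, 1L]:runs[i, 2L]]
      gr <- GRanges(as.character(seqnames(bins))[1L], IRanges(s, e),
                    kind = kind,
                    copyRatio = round(median(inRatio), 2L),
                    meanDepthInside = mean(inDepth),
                    genomeMedianDepth = med)
      out[[length(out) + 1L]] <- gr
    }
  }
  if (!length(out)) {
    res <- GRanges()
    mcols(res) <- DataFrame(kind = character(0), copyRatio = numeric(0),
                            meanDepthInside = numeric(0),
                            genomeMedianDepth = numeric(0))
    return(res)
  }
  res <- do.call(c, unname(out))
  res[order(start(res))]
}

# best step position for one boundary: position b maximising the absolute
# difference between the mean depth over (b-w, b-1] and [b, b+w-1); candidates
# clamped to the track, ties broken toward `centre` then smaller coordinate
.refineOneBoundary <- function(d, centre, window, w) {
  L <- length(d)
  lo <- max(centre - window, 2L)
  hi <- min(centre + window, L)
  if (lo > hi) return(centre)
  cand <- lo:hi
  cs <- c(0, cumsum(as.numeric(d)))
  leftMean <- function(b) {
    a <- max(1L, b - w)
    (cs[b] - cs[a]) / (b - a)
  }
  rightMean <- function(b) {
    e <- min(L, b + w - 1L)
    (cs[e + 1L] - cs[b]) / (e - b + 1L)
  }
  score <- abs(vapply(cand, rightMean, 0) - vapply(cand, leftMean, 0))
  best <- which(score == max(score))
  if (length(best) > 1L) {
    dd <- abs(cand[best] - centre)
    best <- best[dd == min(dd)]
    best <- best[1L]  # remaining ties: smaller coordinate
  }
  cand[best]
}

#' Refine call boundaries to base resolution
#'
#' For each boundary of a bin-resolution call, searches `boundary +/-
#' refineWindow` on the per-base track for the base `b` maximising the absolute
#' contrast `|mean(depth in (b-w, b-1]) - mean(depth in [b, b+w-1))|` with
#' `w = refineWindow/2`. The segment start is refined directly; the end is
#' refined at its first-base-after position and converted back. Ties break
#' toward the unrefined boundary, then toward the smaller coordinate; windows
#' running off the contig are clamped with a warning.
#'
#' @param calls [GenomicRanges::GRanges] from [callSegments()].
#' @param track the per-base [DepthTrack-class].
#' @param refineWindow search half-width in bases.
#' @return The calls with refined `start`/`end`.
#' @export
refineBoundaries <- function(calls, track, refineWindow = 2000L) {
  stopifnot(is(track, "DepthTrack"))
  if (!length(calls)) return(calls)
  d <- as.numeric(depthValues(track))
  L <- length(d)
  w <- max(1L, as.integer(refineWindow) %/% 2L)
  win <- as.integer(refineWindow)
  newStart <- start(calls); newEnd <- end(calls)
  for (i in seq_along(calls)) {
    s <- newStart[i]; e <- newEnd[i]
    if (s - win < 1L || e + 1L + win > L)
      warning("refinement window clamped at a contig edge")
    ns <- .refineOneBoundary(d, s, win, w)
    ne <- .refineOneBoundary(d, e + 1L, win, w) - 1L
    if (ne >= ns) {
      newStart[i] <- ns
      newEnd[i] <- ne
    }
  }
  ranges(calls) <- IRanges(newStart, newEnd, names = names(calls))
  calls
}

#' Estimate a call's copy ratio
#'
#' Median of the normalised bin ratios inside the call, reported to 2 decimals.
#' A population carrying the chromosome plus one extrachromosomal copy of a
#' segment shows a ratio near 2; the observed megatransposon signal is ~2.2.
#'
#' @param call a single-element [GenomicRanges::GRanges].
#' @param bins output of [binAndNormalize()].
#' @return Numeric copy-ratio estimate (2 decimals).
#' @export
estimateCopyRatio <- function(call, bins) {
  if (length(call) != 1L)
    mtxStop("invalid_parameter", "'call' must be a single range")
  idx <- which(start(bins) <= end(call) & end(bins) >= start(call))
  if (!length(idx))
    mtxStop("invalid_parameter", "call covers no bins")
  round(median(bins$ratio[idx]), 2L)
}

#' Read a depth track from bedGraph or TSV
#'
#' bedGraph intervals (0-based half-open on disk) are read with rtracklayer and
#' expanded to per-base 1-based depth; the 2-column TSV format is 1-based
#' `position<TAB>depth`. Positions not covered by any interval get depth 0.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bedGraph"` or `"tsv"`.
#' @return A [DepthTrack-class].
#' @seealso [writeDepthTrack()]
#' @export
readDepthTrack <- function(path, format = c("auto", "bedGraph", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", tolower(path))) "bedGraph" else "tsv"
  if (format == "bedGraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!length(gr)) mtxStop("degenerate_input", "empty bedGraph: %s", path)
    L <- max(end(gr))
    d <- rep(0, L)
    for (i in seq_along(gr)) d[start(gr)[i]:end(gr)[i]] <- gr$score[i]
    DepthTrack(d, contig = as.character(seqnames(gr))[1L])
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("pos", "depth"))
    L <- max(tab$pos)
    d <- rep(0, L)
    d[tab$pos] <- tab$depth
    DepthTrack(d)
  }
}

#' Report segment calls with both length conventions
#'
#' Published coordinates are often accompanied by a "span" computed as
#' `end - start`, one less than the inclusive length `end - start + 1`; circle
#' sizes sum inclusive lengths. Reports therefore carry both, labelled.
#'
#' @param calls [GenomicRanges::GRanges] of calls.
#' @return A data.frame with columns `name`, `contig`, `start`, `end`,
#'   `inclusiveLength`, `span`, `kind`, `copyRatio`.
#' @export
segmentReport <- function(calls) {
  nm <- names(calls)
  if (is.null(nm)) nm <- paste0(substr(calls$kind, 1, 3), seq_along(calls))
  data.frame(
    name = nm,
    contig = if (length(calls)) as.character(seqnames(calls)) else character(0),
    start = start(calls), end = end(calls),
    inclusiveLength = width(calls),
    span = end(calls) - start(calls),
    kind = calls$kind,
    copyRatio = calls$copyRatio,
    row.names = NULL)
}

#' Write segment calls as BED and JSON
#'
#' BED output is 0-based half-open; the JSON report mirrors [segmentReport()]
#' with both length conventions.
#'
#' @param calls [GenomicRanges::GRanges] of calls.
#' @param bedPath,jsonPath output files (either may be NULL to skip).
#' @return The report data.frame, invisibly.
#' @export
writeSegmentCalls <- function(calls, bedPath = NULL, jsonPath = NULL) {
  rep <- segmentReport(calls)
  if (!is.null(bedPath)) {
    bed <- data.frame(chrom = rep$contig, chromStart = rep$start - 1L,
                      chromEnd = rep$end, name = rep$name,
                      score = round(rep$copyRatio * 100),
                      strand = ".")
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(jsonPath))
    jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
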