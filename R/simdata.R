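# Synthetic data: genomes, circular elements, depth tracks and long reads with
# known truth, so the whole calling/quantification/reconstruction chain is
# testable without any sequencing data.

#' Generate a random genome sequence
#'
#' Draws an i.i.d. nucleotide sequence with a target GC fraction. Used as the
#' chromosome backbone for simulation scenarios.
#'
#' @param length genome length in bases (at least 1000).
#' @param gcFraction target GC content in `[0, 1]`; G and C (and A and T) are
#'   equiprobable within their pair.
#' @param seed integer seed; the same `(length, gcFraction, seed)` always
#'   yields the identical sequence.
#' @param name sequence name.
#' @return A named [Biostrings::DNAStringSet] of length 1.
#' @examples
#' g <- generateGenome(10000, 0.5, seed = 1)
#' Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)
#' @export
generateGenome <- function(length, gcFraction = 0.5, seed, name = "chr") {
  if (length < 1000)
    mtxStop("invalid_parameter", "genome length must be >= 1000 (got %s)", length)
  if (gcFraction < 0 || gcFraction > 1)
    mtxStop("invalid_parameter", "gcFraction must be in [0, 1]")
  letters <- withSeed(seed, {
    sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
           prob = c((1 - gcFraction) / 2, gcFraction / 2,
                    gcFraction / 2, (1 - gcFraction) / 2))
  })
  out <- DNAStringSet(paste(letters, collapse = ""))
  names(out) <- name
  out
}

#' Build a circular-element scenario from two duplicated segments
#'
#' Models the observed geometry of a CO-dependent megatransposon: two forward
#' chromosomal segments, separated by a gap that is skipped, joined into one
#' circular element. The circle sequence is `seq(dup1) . seq(dup2)` read
#' circularly, so its two adjacencies (end-of-dup1 to start-of-dup2 and
#' end-of-dup2 back to start-of-dup1) exist on the circle but not on the
#' chromosome.
#'
#' @param genome reference chromosome ([Biostrings::DNAStringSet] of length 1
#'   or [Biostrings::DNAString]).
#' @param dup1,dup2 1-based inclusive `c(start, end)` coordinates of the two
#'   segments; `dup2` must start after `dup1` ends (non-overlapping, forward).
#' @param flankK flank length used for the truth junctions (default 25,
#'   giving 50 bp junction sequences).
#' @return A list with elements `circle` (a [ReconstructedCircle-class]),
#'   `layout` (the [CircleLayout-class]), `junctions` (the truth
#'   [JunctionSet-class]), and `segments` (GRanges of the two duplications).
#' @examples
#' g <- generateGenome(5000, 0.5, seed = 3)
#' sc <- buildScenario(g, dup1 = c(101, 200), dup2 = c(301, 350))
#' length(sc$circle)  # 100 + 50
#' @export
buildScenario <- function(genome, dup1, dup2, flankK = 25L) {
  gseq <- asDNAString(genome, "genome")
  L <- length(gseq)
  chk <- function(x, nm) {
    if (length(x) != 2L || anyNA(x) || x[1] < 1 || x[2] > L || x[1] > x[2])
      mtxStop("invalid_interval", "'%s' must be c(start, end) within the genome", nm)
  }
  chk(dup1, "dup1"); chk(dup2, "dup2")
  if (dup2[1] <= dup1[2])
    mtxStop("invalid_interval",
            "dup2 must start after dup1 ends (got dup1 end %d, dup2 start %d)",
            dup1[2], dup2[1])
  nm <- if (is(genome, "DNAStringSet") && !is.null(names(genome))) names(genome)[1] else "chr"
  seg <- GRanges(nm, IRanges(c(dup1[1], dup2[1]), c(dup1[2], dup2[2])),
                 strand = "+")
  names(seg) <- c("dup1", "dup2")
  layout <- CircleLayout(seg)
  circle <- assembleCircle(layout, gseq)
  junctions <- buildJunctions(layout, gseq, flankK = flankK)
  list(circle = circle, layout = layout, junctions = junctions, segments = seg)
}

#' Simulate a per-base depth track
#'
#' Draws per-base depth as independent `Poisson(meanDepth * copyRatio(base))`,
#' with copy ratio 1 outside the supplied events. This emulates the coverage
#' profile of uniformly sampled short reads over a genome carrying duplications
#' (copy ratio > 1) or deletions (copy ratio 0), without running an aligner.
#'
#' @param genomeLength track length in bases (a genome object is also
#'   accepted).
#' @param events [GenomicRanges::GRanges] with a numeric metadata column
#'   `copyRatio` (>= 0; 0 encodes a homozygous deletion), or NULL for none.
#'   Events must not overlap.
#' @param meanDepth background mean depth (copy ratio 1), > 0.
#' @param seed integer seed.
#' @param contig contig name for the resulting track.
#' @return A [DepthTrack-class].
#' @examples
#' ev <- GenomicRanges::GRanges("chr", IRanges::IRanges(2001, 4000), copyRatio = 2.2)
#' dt <- simulateDepthTrack(10000, ev, meanDepth = 100, seed = 11)
#' mean(S4Vectors::runValue(depthValues(dt)))
#' @export
simulateDepthTrack <- function(genomeLength, events = NULL, meanDepth, seed,
                               contig = "chr") {
  if (!is.numeric(genomeLength))
    genomeLength <- length(asDNAString(genomeLength, "genomeLength"))
  L <- as.integer(genomeLength)
  if (meanDepth <= 0)
    mtxStop("invalid_parameter", "meanDepth must be > 0")
  ratio <- rep(1, L)
  if (!is.null(events) && length(events)) {
    if (is.null(events$copyRatio) || any(events$copyRatio < 0))
      mtxStop("invalid_parameter", "events need a non-negative 'copyRatio' column")
    if (length(events) > 1L) {
      o <- order(start(events))
      if (any(start(events)[o][-1] <= end(events)[o][-length(events)]))
        mtxStop("invalid_parameter", "events must not overlap")
    }
    for (i in seq_along(events)) {
      ratio[start(events)[i]:end(events)[i]] <- events$copyRatio[i]
    }
  }
  d <- withSeed(seed, rpois(L, lambda = meanDepth * ratio))
  DepthTrack(d, contig = contig)
}

# default read-length model: truncated lognormal with median matching the
# observed raw-ONT N50-scale run (median 5697 bp), capped at 50 kb
.defaultReadSimParams <- list(
  totalBases = 1e6,
  meanLog = log(5697),
  sdLog = 0.6,
  minLen = 100L,
  maxLen = 50000L,
  subRate = 0.02,
  insRate = 0.015,
  delRate = 0.02
)

#' Parameters for long-read simulation
#'
#' Read lengths are lognormal (`meanLog`, `sdLog`) truncated to
#' `[minLen, maxLen]`; errors are i.i.d. per-base substitutions, insertions and
#' deletions. Defaults emulate a raw nanopore run with median read length
#' 5,697 bp and moderate error (2% sub / 1.5% ins / 2% del).
#'
#' @param totalBases target total simulated bases; simulation stops at the
#'   first read reaching the target (total within one read of it).
#' @param meanLog,sdLog lognormal log-scale mean and sd of read length.
#' @param minLen,maxLen truncation bounds in bases.
#' @param subRate,insRate,delRate per-base error probabilities, each in
#'   `[0, 0.3]`.
#' @return A named list of validated parameters.
#' @export
readSimParams <- function(totalBases = 1e6,
                          meanLog = log(5697), sdLog = 0.6,
                          minLen = 100L, maxLen = 50000L,
                          subRate = 0.02, insRate = 0.015, delRate = 0.02) {
  p <- list(totalBases = totalBases, meanLog = meanLog, sdLog = sdLog,
            minLen = as.integer(minLen), maxLen = as.integer(maxLen),
            subRate = subRate, insRate = insRate, delRate = delRate)
  if (p$totalBases <= 0)
    mtxStop("invalid_parameter", "totalBases must be > 0")
  rates <- c(p$subRate, p$insRate, p$delRate)
  if (any(rates < 0) || any(rates > 0.3))
    mtxStop("invalid_parameter", "error rates must lie in [0, 0.3]")
  if (p$minLen < 1L || p$maxLen < p$minLen)
    mtxStop("invalid_parameter", "need 1 <= minLen <= maxLen")
  p
}

# apply iid substitution/insertion/deletion errors to one read (character
# scalar); vectorised over positions within the read
.applyReadErrors <- function(s, subRate, insRate, delRate) {
  if (subRate == 0 && insRate == 0 && delRate == 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  bases <- c("A", "C", "G", "T")
  sub <- runif(n) < subRate
  if (any(sub)) {
    # substitute with a uniformly chosen *different* base
    cur <- match(v[sub], bases)
    off <- sample.int(3L, sum(sub), replace = TRUE)
    v[sub] <- bases[((cur - 1L + off) %% 4L) + 1L]
  }
  del <- runif(n) < delRate
  ins <- runif(n) < insRate
  if (any(del) || any(ins)) {
    pieces <- v
    pieces[del] <- ""
    if (any(ins)) {
      w <- which(ins)
      pieces[w] <- paste0(pieces[w], sample(bases, length(w), replace = TRUE))
    }
    v <- pieces
  }
  paste(v, collapse = "")
}

#' Simulate long reads from linear and circular molecules
#'
#' Reads are drawn molecule by molecule with probability proportional to
#' `weight * length(molecule)`; start positions are uniform on the molecule.
#' On circular molecules reads may wrap around the origin; on linear molecules
#' reads running off the 3' end are truncated there. Lengths follow the
#' truncated lognormal of [readSimParams()]; i.i.d. errors are applied
#' afterwards. Simulation stops at the first read that reaches
#' `params$totalBases` (error-free length accounting), so the total is within
#' one read of the target.
#'
#' @param sources a list of sources, each a list with elements `seq` (DNA
#'   sequence), `circular` (logical) and `weight` (>= 0); names are used as
#'   molecule names in the truth records.
#' @param params a [readSimParams()] list.
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet] of reads whose [S4Vectors::mcols()]
#'   carry the truth: `source`, `start` (1-based on the source), `strand`,
#'   `trueLength` (error-free length drawn). `metadata()` records
#'   `totalTrueBases` (sum of truth lengths, the normalisation denominator for
#'   error-free reads).
#' @examples
#' g <- generateGenome(20000, 0.5, seed = 5)
#' src <- list(chr = list(seq = g[[1]], circular = FALSE, weight = 1))
#' rd <- simulateLongReads(src, readSimParams(totalBases = 1e5, subRate = 0,
#'                                            insRate = 0, delRate = 0), seed = 9)
#' sum(Biostrings::width(rd))
#' @export
simulateLongReads <- function(sources, params = readSimParams(), seed) {
  if (length(sources) == 0L)
    mtxStop("invalid_parameter", "'sources' must not be empty")
  if (is.null(names(sources))) names(sources) <- paste0("mol", seq_along(sources))
  seqs <- lapply(sources, function(s) asDNAString(s$seq, "source seq"))
  circ <- vapply(sources, function(s) isTRUE(s$circular), logical(1))
  wt <- vapply(sources, function(s) as.numeric(s$weight), numeric(1))
  if (anyNA(wt) || any(wt < 0) || all(wt == 0))
    mtxStop("invalid_parameter", "source weights must be >= 0 with at least one positive")
  lens <- vapply(seqs, length, integer(1))
  prob <- wt * lens
  prob <- prob / sum(prob)

  withSeed(seed, {
    # draw in blocks until the base budget is reached
    reads <- character(0)
    recSource <- character(0); recStart <- integer(0)
    recStrand <- character(0); recLen <- integer(0)
    total <- 0
    while (total < params$totalBases) {
      nblk <- max(16L, ceiling((params$totalBases - total) /
                                 exp(params$meanLog + params$sdLog^2 / 2)))
      ln <- round(rlnorm(nblk, params$meanLog, params$sdLog))
      ln <- pmin(pmax(ln, params$minLen), params$maxLen)
      srcIdx <- sample.int(length(seqs), nblk, replace = TRUE, prob = prob)
      strands <- sample(c("+", "-"), nblk, replace = TRUE)
      starts <- integer(nblk)
      for (j in seq_len(nblk)) {
        if (total >= params$totalBases) break
        i <- srcIdx[j]
        L <- lens[i]
        st <- sample.int(L, 1L)
        len <- as.integer(ln[j])
        if (circ[i]) {
          len <- min(len, L)
          frag <- circularSubseq(seqs[[i]], st, len)
        } else {
          len <- min(len, L - st + 1L)
          frag <- subseq(seqs[[i]], st, st + len - 1L)
        }
        if (strands[j] == "-") frag <- reverseComplement(frag)
        rs <- .applyReadErrors(as.character(frag),
                               params$subRate, params$insRate, params$delRate)
        reads <- c(reads, rs)
        recSource <- c(recSource, names(seqs)[i])
        recStart <- c(recStart, st)
        recStrand <- c(recStrand, strands[j])
        recLen <- c(recLen, len)
        total <- total + len
        starts[j] <- st
      }
    }
    out <- DNAStringSet(reads)
    names(out) <- sprintf("read%06d", seq_along(out))
    mcols(out) <- DataFrame(source = recSource, start = recStart,
                            strand = recStrand, trueLength = recLen)
    metadata(out) <- list(totalTrueBases = total)
    out
  })
}

#' Write simulated reads to FASTQ
#'
#' Writes reads with a uniform dummy quality ('I' for every base); qualities
#' are never used downstream.
#'
#' @param reads a [Biostrings::DNAStringSet] (e.g. from [simulateLongReads()]).
#' @param path output file; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(vapply(width(reads),
                                         function(w) strrep("I", w), ""))
  writeXStringSet(reads, path, format = "fastq", qualities = quals,
                  compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Emit paired-free synthetic short reads (optional helper)
#'
#' Uniform error-free short reads from a genome, for users who want to exercise
#' an external aligner; the depth-track simulator is the supported in-package
#' route and no analysis step here requires alignment.
#'
#' @param genome genome sequence.
#' @param readLength read length in bases.
#' @param nReads number of reads.
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
simulateShortReads <- function(genome, readLength = 150L, nReads, seed) {
  gseq <- asDNAString(genome, "genome")
  L <- length(gseq)
  if (readLength > L) mtxStop("invalid_parameter", "readLength exceeds the genome")
  withSeed(seed, {
    st <- sample.int(L - readLength + 1L, nReads, replace = TRUE)
    strands <- sample(c("+", "-"), nReads, replace = TRUE)
    out <- DNAStringSet(gseq, start = st, width = readLength)
    rc <- strands == "-"
    if (any(rc)) out[rc] <- reverseComplement(out[rc])
    names(out) <- sprintf("sr%06d", seq_len(nReads))
    out
  })
}

#' Write a depth track to disk
#'
#' Two plain-text formats are supported: 4-column bedGraph (0-based half-open,
#' run-length compressed) via rtracklayer, and 2-column TSV
#' (1-based position, depth).
#'
#' @param track a [DepthTrack-class].
#' @param path output file.
#' @param format `"bedGraph"` or `"tsv"`.
#' @return `path`, invisibly.
#' @seealso [readDepthTrack()]
#' @export
writeDepthTrack <- function(track, path, format = c("bedGraph", "tsv")) {
  format <- match.arg(format)
  d <- depthValues(track)
  if (format == "bedGraph") {
    ends <- cumsum(runLength(d))
    gr <- GRanges(contigName(track),
                  IRanges(start = c(1L, head(ends, -1L) + 1L), end = ends),
                  score = runValue(d))
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    utils::write.table(
      data.frame(pos = seq_len(length(d)), depth = as.numeric(d)),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Serialise a simulation truth set to JSON
#'
#' Records the true segments (with copy ratios), the truth junction sequences
#' and the circle length, so downstream calls can be scored against the truth.
#'
#' @param scenario result of [buildScenario()].
#' @param copyRatios named numeric vector of true copy ratios per segment
#'   (optional).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeTruthJson <- function(scenario, copyRatios = NULL, path) {
  seg <- scenario$segments
  truth <- list(
    segments = data.frame(
      name = names(seg), contig = as.character(seqnames(seg)),
      start = start(seg), end = end(seg),
      copyRatio = if (is.null(copyRatios)) NA_real_ else
        unname(copyRatios[names(seg)])),
    junctions = as.list(setNames(as.character(scenario$junctions),
                                 names(scenario$junctions))),
    circleLength = length(scenario$circle)
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
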