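# Circle-specific junction sequences: construction from segment ends,
# genomic-absence checking, read scanning (exact or bounded edit distance) and
# depth-normalised quantification.

# oriented sequence of one layout segment on the reference
.orientedSegSeq <- function(reference, seg, i) {
  s <- subseq(reference, start(seg)[i], end(seg)[i])
  if (as.character(strand(seg))[i] == "-") s <- reverseComplement(s)
  s
}

#' Build junction sequences from a circular layout
#'
#' For each adjacency of the circular layout (end of segment i joined to start
#' of segment i+1, cyclically) the junction is the last `flankK` bases
#' contributed by the upstream oriented segment followed by the first `flankK`
#' bases contributed by the downstream one — a 2k-mer (50 bp at the default
#' k = 25) that exists on the circle but not, if the element is real and
#' specific, anywhere on the chromosome. A single-segment circle yields one
#' head-to-tail junction.
#'
#' @param layout a [CircleLayout-class].
#' @param reference the chromosome sequence the layout coordinates refer to.
#' @param flankK per-side flank length in bases (default 25).
#' @return A [JunctionSet-class] with one junction per adjacency, named
#'   `"<from>|<to>"`; metadata columns record the joined segment names and
#'   orientations.
#' @examples
#' g <- generateGenome(5000, 0.5, seed = 2)
#' sc <- buildScenario(g, c(1001, 2000), c(3001, 3500))
#' buildJunctions(sc$layout, g, flankK = 25)
#' @export
buildJunctions <- function(layout, reference, flankK = 25L) {
  ref <- asDNAString(reference, "reference")
  seg <- layoutSegments(layout)
  flankK <- as.integer(flankK)
  if (any(width(seg) < flankK))
    mtxStop("invalid_parameter",
            "flankK (%d) exceeds the shortest segment (%d bp)",
            flankK, min(width(seg)))
  n <- length(seg)
  seqs <- lapply(seq_len(n), function(i) .orientedSegSeq(ref, seg, i))
  nxt <- c(seq_len(n)[-1L], 1L)
  jn <- vapply(seq_len(n), function(i) {
    left <- subseq(seqs[[i]], length(seqs[[i]]) - flankK + 1L, length(seqs[[i]]))
    right <- subseq(seqs[[nxt[i]]], 1L, flankK)
    as.character(xscat(left, right))
  }, character(1))
  jset <- DNAStringSet(jn)
  names(jset) <- sprintf("%s%s|%s%s",
                         names(seg), as.character(strand(seg)),
                         names(seg)[nxt], as.character(strand(seg))[nxt])
  out <- new("JunctionSet", jset, flankK = flankK)
  mcols(out) <- DataFrame(fromSegment = names(seg),
                          fromStrand = as.character(strand(seg)),
                          toSegment = names(seg)[nxt],
                          toStrand = as.character(strand(seg))[nxt])
  out
}

#' Check that junctions are absent from the reference
#'
#' A junction is *specific* (diagnostic of the circular element) iff neither
#' the junction sequence nor its reverse complement occurs as an exact
#' substring of the reference. The reference is treated as linear unless
#' `circular = TRUE`, in which case the origin-spanning window is also
#' searched.
#'
#' @param junctions a [JunctionSet-class] (or DNAStringSet).
#' @param reference reference sequence.
#' @param circular is the reference molecule circular?
#' @return A [S4Vectors::DataFrame] with per-junction columns `specific`
#'   (logical) and `positions` (IntegerList of 1-based match starts, reverse
#'   complement hits included, origin-window hits mapped back).
#' @export
checkSpecificity <- function(junctions, reference, circular = FALSE) {
  ref <- asDNAString(reference, "reference")
  L <- length(ref)
  pos <- vector("list", length(junctions))
  for (i in seq_along(junctions)) {
    j <- junctions[[i]]
    wj <- length(j)
    subject <- if (circular && L > wj)
      xscat(ref, subseq(ref, 1L, wj - 1L)) else ref
    hits <- c(start(matchPattern(j, subject)),
              start(matchPattern(reverseComplement(j), subject)))
    hits <- sort(unique(((hits - 1L) %% L) + 1L))
    pos[[i]] <- hits
  }
  DataFrame(specific = lengths(pos) == 0L,
            positions = IRanges::IntegerList(pos),
            row.names = names(junctions))
}

#' Matching parameters for read scanning
#'
#' @param maxEdits maximum edit distance (substitutions + indels) allowed
#'   between a junction and a read substring; 0 (the default) is exact
#'   matching, mirroring raw-read selection by exact 50-mer content. A
#'   noisy-read preset of 3 is useful because with i.i.d. per-base error e the
#'   chance of an error-free 50-mer is only about `(1-e)^50`.
#' @param scanBothStrands also match the reverse complement of each junction
#'   (default TRUE).
#' @param flankK flank length of the junctions being scanned (used to validate
#'   `maxEdits <= flankK/2`).
#' @return A validated named list.
#' @export
matchParams <- function(maxEdits = 0L, scanBothStrands = TRUE, flankK = 25L) {
  maxEdits <- as.integer(maxEdits)
  if (maxEdits < 0L)
    mtxStop("invalid_parameter", "maxEdits must be >= 0")
  if (maxEdits > flankK / 2)
    mtxStop("invalid_parameter", "maxEdits must not exceed flankK/2")
  list(maxEdits = maxEdits, scanBothStrands = isTRUE(scanBothStrands),
       flankK = as.integer(flankK))
}

# load reads from a path (FASTA/FASTQ, optionally gz) or pass through a
# DNAStringSet
.loadReads <- function(reads) {
  if (is(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1L) {
    fq <- grepl("\\.(fastq|fq)(\\.gz)?$", tolower(reads))
    return(readDNAStringSet(reads, format = if (fq) "fastq" else "fasta"))
  }
  mtxStop("invalid_parameter", "'reads' must be a file path or a DNAStringSet")
}

#' Scan reads for junction sequences
#'
#' A read is a *hit* for a junction iff the junction (or, with
#' `scanBothStrands`, its reverse complement) matches a substring of the read
#' with edit distance at most `maxEdits` — semi-global matching: the junction
#' aligns end-to-end, the read provides free ends. Each read counts at most
#' once per junction, regardless of how many times the junction occurs in it;
#' a read containing several junctions increments each of their counters once.
#' Counts are normalised by the total bases in the read set as provided (raw,
#' untrimmed), reported as reads per gigabase.
#'
#' @param reads FASTA/FASTQ path (gz accepted) or [Biostrings::DNAStringSet].
#' @param junctions a [JunctionSet-class] (or named DNAStringSet).
#' @param params a [matchParams()] list.
#' @param keepIds keep the ids of hit reads per junction (default TRUE).
#' @return A list of class `junctionHitReport`: `table` (data.frame with
#'   columns `junction`, `readCount`, `totalBases`, `readsPerGb`, `presence`),
#'   `hitIds` (list of character vectors), `totalBases`, `nReads`, and
#'   `params`. With an empty read set `readsPerGb` is `NA` and the report is
#'   flagged via `empty = TRUE`.
#' @examples
#' g <- generateGenome(20000, 0.5, seed = 4)
#' sc <- buildScenario(g, c(2001, 6000), c(9001, 11000))
#' src <- list(circle = list(seq = circleSequence(sc$circle), circular = TRUE,
#'                           weight = 1))
#' rd <- simulateLongReads(src, readSimParams(totalBases = 2e5, meanLog = log(2000),
#'                         sdLog = 0.3, subRate = 0, insRate = 0, delRate = 0),
#'                         seed = 8)
#' scanReads(rd, sc$junctions)$table
#' @export
scanReads <- function(reads, junctions, params = matchParams(), keepIds = TRUE) {
  rset <- .loadReads(reads)
  totalBases <- sum(as.numeric(width(rset)))
  nj <- length(junctions)
  jnames <- names(junctions)
  if (is.null(jnames)) jnames <- paste0("J", seq_len(nj))
  counts <- integer(nj)
  hitIds <- rep(list(character(0)), nj)
  if (length(rset)) {
    for (i in seq_len(nj)) {
      j <- junctions[[i]]
      if (length(j) < 2L * params$maxEdits + 1L)
        mtxStop("invalid_parameter",
                "junction '%s' too short for maxEdits = %d", jnames[i],
                params$maxEdits)
      hit <- vcountPattern(j, rset, max.mismatch = params$maxEdits,
                           with.indels = params$maxEdits > 0L) > 0L
      if (params$scanBothStrands) {
        hit <- hit | (vcountPattern(reverseComplement(j), rset,
                                    max.mismatch = params$maxEdits,
                                    with.indels = params$maxEdits > 0L) > 0L)
      }
      counts[i] <- sum(hit)
      if (keepIds) hitIds[[i]] <- names(rset)[hit]
    }
  }
  rpg <- if (totalBases > 0) counts / (totalBases / 1e9) else rep(NA_real_, nj)
  out <- list(
    table = data.frame(junction = jnames, readCount = counts,
                       totalBases = totalBases, readsPerGb = rpg,
                       presence = counts >= 1L, row.names = NULL),
    hitIds = setNames(hitIds, jnames),
    totalBases = totalBases, nReads = length(rset),
    empty = length(rset) == 0L,
    params = params)
  class(out) <- "junctionHitReport"
  out
}

#' @export
print.junctionHitReport <- function(x, ...) {
  cat(sprintf("Junction scan: %d read(s), %.0f bases, maxEdits = %d\n",
              x$nReads, x$totalBases, x$params$maxEdits))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Call junction presence from a scan report
#'
#' @param report a [scanReads()] report.
#' @param minReads minimum hit reads for a junction to be called present
#'   (default 1).
#' @return Named logical vector, one flag per junction.
#' @export
callPresence <- function(report, minReads = 1L) {
  setNames(report$table$readCount >= minReads, report$table$junction)
}

#' Write a junction scan report as TSV and/or JSON
#'
#' @param report a [scanReads()] report.
#' @param tsvPath,jsonPath,hitIdsPath output files (NULL to skip).
#' @return The report table, invisibly.
#' @export
writeJunctionReport <- function(report, tsvPath = NULL, jsonPath = NULL,
                                hitIdsPath = NULL) {
  if (!is.null(tsvPath))
    utils::write.table(report$table, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(table = report$table, totalBases = report$totalBases,
           nReads = report$nReads, maxEdits = report$params$maxEdits),
      jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(hitIdsPath)) {
    lines <- unlist(lapply(names(report$hitIds), function(j)
      if (length(report$hitIds[[j]]))
        paste(j, report$hitIds[[j]], sep = "\t") else character(0)))
    writeLines(lines, hitIdsPath)
  }
  invisible(report$table)
}

#' Read/write junctions as FASTA or JSON
#'
#' @param junctions a [JunctionSet-class].
#' @param path output file; `.json` selects JSON, anything else FASTA.
#' @return `path`, invisibly.
#' @export
writeJunctions <- function(junctions, path) {
  if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(
      list(flankK = flankK(junctions),
           junctions = as.list(setNames(as.character(junctions),
                                        names(junctions)))),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    writeXStringSet(junctions, path)
  }
  invisible(path)
}

#' @rdname writeJunctions
#' @export
readJunctions <- function(path) {
  if (grepl("\\.json$", tolower(path))) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- DNAStringSet(unlist(obj$junctions))
    new("JunctionSet", out, flankK = as.integer(obj$flankK))
  } else {
    out <- readDNAStringSet(path)
    k <- unique(width(out)) / 2L
    if (length(k) != 1L || k != as.integer(k))
      mtxStop("invalid_parameter", "junction FASTA must hold equal even widths")
    new("JunctionSet", out, flankK = as.integer(k))
  }
}
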