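# Reference-guided reconstruction of the circular element: candidate junction
# enumeration, read-support scoring, greedy layout resolution with ambiguity
# detection, assembly, and anchor rotation.

# canonical key of a junction sequence up to reverse complement
.canonKey <- function(s) {
  rc <- as.character(reverseComplement(DNAString(s)))
  if (s <= rc) s else rc
}

#' Enumerate candidate adjacencies between called segments
#'
#' Builds the junction 2k-mer for every ordered pair of oriented segments
#' (self-joins included): the out-end of `(a, oa)` joined to the in-end of
#' `(b, ob)`. Candidates identical up to reverse complement describe the same
#' physical adjacency and are collapsed to one representative; candidates
#' whose sequence already occurs in the reference (reference adjacencies,
#' e.g. two abutting calls) are flagged `isReferenceAdjacency` and are
#' excluded from layout resolution. Two segments yield 8 distinct candidate
#' classes; one segment yields 3 (head-to-tail plus a foldback at each end).
#'
#' @param segments named [GenomicRanges::GRanges] of duplication calls (at
#'   least one).
#' @param reference chromosome sequence.
#' @param flankK per-side flank length (default 25).
#' @return A [JunctionSet-class]; metadata columns `fromSegment`, `fromStrand`,
#'   `toSegment`, `toStrand`, `isReferenceAdjacency`.
#' @export
enumerateCandidates <- function(segments, reference, flankK = 25L) {
  ref <- asDNAString(reference, "reference")
  if (length(segments) < 1L)
    mtxStop("invalid_parameter", "need at least one segment")
  if (is.null(names(segments)))
    names(segments) <- paste0("seg", seq_along(segments))
  flankK <- as.integer(flankK)
  if (any(width(segments) < flankK))
    mtxStop("invalid_parameter", "flankK (%d) exceeds the shortest segment",
            flankK)
  n <- length(segments)
  segSeq <- list()
  for (nm in names(segments)) {
    i <- match(nm, names(segments))
    fwd <- subseq(ref, start(segments)[i], end(segments)[i])
    segSeq[[paste0(nm, "+")]] <- fwd
    segSeq[[paste0(nm, "-")]] <- reverseComplement(fwd)
  }
  combos <- expand.grid(a = names(segments), oa = c("+", "-"),
                        b = names(segments), ob = c("+", "-"),
                        stringsAsFactors = FALSE)
  seen <- character(0)
  keep <- list()
  for (r in seq_len(nrow(combos))) {
    sa <- segSeq[[paste0(combos$a[r], combos$oa[r])]]
    sb <- segSeq[[paste0(combos$b[r], combos$ob[r])]]
    jseq <- as.character(xscat(subseq(sa, length(sa) - flankK + 1L, length(sa)),
                               subseq(sb, 1L, flankK)))
    key <- .canonKey(jseq)
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1L]] <- data.frame(
      seq = jseq, from = combos$a[r], fromStrand = combos$oa[r],
      to = combos$b[r], toStrand = combos$ob[r])
  }
  tab <- do.call(rbind, keep)
  isRef <- vapply(tab$seq, function(s) {
    j <- DNAString(s)
    countPattern(j, ref) > 0L || countPattern(reverseComplement(j), ref) > 0L
  }, logical(1))
  jset <- DNAStringSet(tab$seq)
  names(jset) <- sprintf("%s%s|%s%s", tab$from, tab$fromStrand,
                         tab$to, tab$toStrand)
  out <- new("JunctionSet", jset, flankK = flankK)
  mcols(out) <- DataFrame(fromSegment = tab$from, fromStrand = tab$fromStrand,
                          toSegment = tab$to, toStrand = tab$toStrand,
                          isReferenceAdjacency = unname(isRef))
  out
}

#' Score candidate adjacencies by read support
#'
#' One pass of [scanReads()] over the read set; each candidate's support is
#' the number of reads matching its junction sequence.
#'
#' @param candidates a [JunctionSet-class] from [enumerateCandidates()].
#' @param reads FASTA/FASTQ path or [Biostrings::DNAStringSet].
#' @param params a [matchParams()] list.
#' @return A data.frame (junction evidence table): `junction`, `fromSegment`,
#'   `fromStrand`, `toSegment`, `toStrand`, `isReferenceAdjacency`,
#'   `supportingReads`, `readsPerGb`.
#' @export
scoreCandidates <- function(candidates, reads, params = matchParams()) {
  rep <- scanReads(reads, candidates, params, keepIds = FALSE)
  m <- mcols(candidates)
  data.frame(
    junction = names(candidates),
    fromSegment = m$fromSegment, fromStrand = m$fromStrand,
    toSegment = m$toSegment, toStrand = m$toStrand,
    isReferenceAdjacency = if (!is.null(m$isReferenceAdjacency))
      m$isReferenceAdjacency else FALSE,
    supportingReads = rep$table$readCount,
    readsPerGb = rep$table$readsPerGb,
    sequence = as.character(candidates),
    row.names = NULL)
}

# unoriented end usage of an adjacency candidate: out-end of (a,oa) and
# in-end of (b,ob); L/R are the genomic left/right ends of each segment
.candidateEnds <- function(from, fromStrand, to, toStrand) {
  outEnd <- paste0(from, ifelse(fromStrand == "+", ".R", ".L"))
  inEnd <- paste0(to, ifelse(toStrand == "+", ".L", ".R"))
  c(outEnd, inEnd)
}

#' Resolve the circular layout from junction evidence
#'
#' Greedy resolution: repeatedly accept the highest-supported non-reference
#' candidate whose two segment ends are both still unused, until all ends are
#' used or no candidate with `supportingReads >= minSupport` remains. At each
#' acceptance, if a rejected competing candidate sharing an end has support at
#' least `best / ambiguityFactor`, resolution aborts with an
#' `ambiguous_layout` error. The accepted adjacencies must chain every segment
#' into a single cycle (a Hamiltonian cycle over the segments), otherwise an
#' `incomplete_circle` error is raised; both errors carry the evidence table.
#'
#' @param evidence data.frame from [scoreCandidates()].
#' @param segments the called segments (named GRanges) the evidence refers to.
#' @param minSupport minimum supporting reads to accept a candidate
#'   (default 3).
#' @param ambiguityFactor competing-support ratio that triggers ambiguity
#'   (default 2).
#' @return A [CircleLayout-class] starting at the first segment in forward
#'   orientation where possible.
#' @export
resolveLayout <- function(evidence, segments, minSupport = 3L,
                          ambiguityFactor = 2) {
  ev <- evidence[!evidence$isReferenceAdjacency, , drop = FALSE]
  ev <- ev[order(-ev$supportingReads), , drop = FALSE]
  segNames <- names(segments)
  endsOf <- lapply(seq_len(nrow(ev)), function(r)
    .candidateEnds(ev$fromSegment[r], ev$fromStrand[r],
                   ev$toSegment[r], ev$toStrand[r]))
  usedEnds <- character(0)
  isAccepted <- logical(nrow(ev))
  accepted <- list()
  for (r in seq_len(nrow(ev))) {
    if (ev$supportingReads[r] < minSupport) break
    ends <- endsOf[[r]]
    if (ends[1] == ends[2] || any(ends %in% usedEnds)) next
    # competing = any other not-accepted candidate sharing an end of this one
    # with support within ambiguityFactor of it
    comp <- vapply(seq_len(nrow(ev)), function(q) {
      if (q == r || isAccepted[q]) return(FALSE)
      if (ev$supportingReads[q] < ev$supportingReads[r] / ambiguityFactor)
        return(FALSE)
      any(endsOf[[q]] %in% ends)
    }, logical(1))
    if (any(comp)) {
      e <- simpleError(sprintf(
        "ambiguous_layout: candidate '%s' (support %d) competes with '%s'",
        ev$junction[r], ev$supportingReads[r],
        paste(ev$junction[comp], collapse = ", ")))
      class(e) <- c("ambiguous_layout", class(e))
      e$evidence <- evidence
      stop(e)
    }
    usedEnds <- c(usedEnds, ends)
    isAccepted[r] <- TRUE
    accepted[[length(accepted) + 1L]] <- ev[r, ]
    if (length(accepted) == length(segNames)) break
  }
  acc <- do.call(rbind, accepted)
  fail <- function(why) {
    e <- simpleError(paste0("incomplete_circle: ", why))
    class(e) <- c("incomplete_circle", class(e))
    e$evidence <- evidence
    stop(e)
  }
  if (is.null(acc) || nrow(acc) < length(segNames))
    fail(sprintf("only %d of %d adjacencies supported at minSupport = %d",
                 if (is.null(acc)) 0L else nrow(acc), length(segNames),
                 minSupport))
  # walk the cycle: adjacency (a,oa)->(b,ob) means oriented b follows oriented a;
  # an accepted candidate also stands for its reverse complement
  # (b,-ob)->(a,-oa)
  nextOf <- list()
  for (i in seq_len(nrow(acc))) {
    k1 <- paste0(acc$fromSegment[i], acc$fromStrand[i])
    v1 <- paste0(acc$toSegment[i], acc$toStrand[i])
    flip <- function(o) if (o == "+") "-" else "+"
    k2 <- paste0(acc$toSegment[i], flip(acc$toStrand[i]))
    v2 <- paste0(acc$fromSegment[i], flip(acc$fromStrand[i]))
    if (!is.null(nextOf[[k1]]) || !is.null(nextOf[[k2]]))
      fail("accepted adjacencies reuse a segment end")
    nextOf[[k1]] <- v1
    nextOf[[k2]] <- v2
  }
  startKey <- paste0(segNames[1L], "+")
  if (is.null(nextOf[[startKey]])) startKey <- paste0(segNames[1L], "-")
  if (is.null(nextOf[[startKey]])) fail("first segment participates in no adjacency")
  order <- character(0)
  cur <- startKey
  for (i in seq_along(segNames)) {
    order <- c(order, cur)
    cur <- nextOf[[cur]]
    if (is.null(cur)) fail("adjacency chain breaks before closing")
  }
  if (cur != startKey) fail("accepted adjacencies do not close a single cycle")
  segPart <- sub("[+-]$", "", order)
  oriPart <- sub("^.*(.)$", "\\1", order)
  if (anyDuplicated(segPart)) fail("cycle visits a segment twice")
  seg <- segments[segPart]
  strand(seg) <- oriPart
  names(seg) <- segPart
  CircleLayout(seg)
}

#' Assemble the circular element from a layout
#'
#' Concatenates the orientation-adjusted inclusive segment sequences in layout
#' order; the assembled length always equals the sum of inclusive segment
#' lengths (`end - start + 1` each), independent of orientation or rotation.
#'
#' @param layout a [CircleLayout-class].
#' @param reference chromosome sequence.
#' @return A [ReconstructedCircle-class], unrotated (anchor 1 = start of the
#'   first layout segment).
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(101, 301), c(200, 350)),
#'                              strand = "+")
#' names(gr) <- c("d1", "d2")
#' g <- generateGenome(1000, 0.5, seed = 1)
#' length(assembleCircle(CircleLayout(gr), g))  # 150
#' @export
assembleCircle <- function(layout, reference) {
  ref <- asDNAString(reference, "reference")
  seg <- layoutSegments(layout)
  parts <- lapply(seq_along(seg), function(i) .orientedSegSeq(ref, seg, i))
  seqn <- do.call(xscat, parts)
  new("ReconstructedCircle", sequence = as(seqn, "DNAString"), layout = layout,
      rotationAnchor = 1L)
}

#' Rotate a circle so the anchor becomes position 1
#'
#' Rotation never changes length or content, only the linearisation point;
#' rotating by the circle length (or by 0) is the identity, and rotations
#' compose additively modulo the length. The default anchor used by the
#' pipeline is the start of the first layout segment; rotating to a known
#' feature (e.g. a transposase gene) is the caller's choice.
#'
#' @param circle a [ReconstructedCircle-class].
#' @param anchor 1-based position on the current sequence to move to
#'   position 1.
#' @return The rotated [ReconstructedCircle-class].
#' @export
rotateToAnchor <- function(circle, anchor) {
  L <- length(circle)
  anchor <- as.integer(anchor)
  if (length(anchor) != 1L || is.na(anchor) || anchor < 1L || anchor > L)
    mtxStop("invalid_parameter", "anchor must be a position in [1, %d]", L)
  if (anchor == 1L) return(circle)
  s <- circleSequence(circle)
  rot <- xscat(subseq(s, anchor, L), subseq(s, 1L, anchor - 1L))
  new("ReconstructedCircle", sequence = as(rot, "DNAString"),
      layout = circleLayout(circle),
      rotationAnchor = as.integer(((circle@rotationAnchor - 1L +
                                      (anchor - 1L)) %% L) + 1L))
}

#' Refine layout boundaries by exact junction support
#'
#' Depth-based boundaries are accurate only to tens of bases; the junction
#' itself pins them exactly. For each adjacency of the layout, all junction
#' 2k-mers built from boundary offsets `(da, db)` within `+/- window` are
#' matched exactly (both strands) against the reads with a single PDict pass;
#' the offset pair with the highest supporting-read count wins, ties going to
#' the smallest offset (i.e. toward the depth-refined boundary, then the
#' smaller coordinate). Each segment end is adjusted once, consistently across
#' the two adjacencies that share it.
#'
#' @param layout a [CircleLayout-class] (bin- or depth-refined boundaries).
#' @param reference chromosome sequence.
#' @param reads read set or path.
#' @param window maximum boundary shift searched, in bases (default 40).
#' @param flankK per-side flank length (default 25).
#' @return A [CircleLayout-class] with base-exact boundaries.
#' @export
refineLayoutWithReads <- function(layout, reference, reads, window = 40L,
                                  flankK = 25L) {
  ref <- asDNAString(reference, "reference")
  rset <- .loadReads(reads)
  seg <- layoutSegments(layout)
  if (any(as.character(strand(seg)) != "+"))
    mtxStop("invalid_parameter",
            "read-based flank refinement supports forward layouts")
  n <- length(seg)
  nxt <- c(seq_len(n)[-1L], 1L)
  window <- as.integer(window)
  offs <- -window:window
  L <- length(ref)
  # offset votes per adjacency: daBest shifts the upstream segment's end,
  # dbBest the downstream segment's start
  endShift <- integer(n); startShift <- integer(n)
  for (i in seq_len(n)) {
    aEnd <- end(seg)[i]
    bStart <- start(seg)[nxt[i]]
    okA <- offs[aEnd + offs - flankK + 1L >= 1L & aEnd + offs <= L]
    okB <- offs[bStart + offs >= 1L & bStart + offs + flankK - 1L <= L]
    grid <- expand.grid(da = okA, db = okB)
    left <- vapply(grid$da, function(da)
      as.character(subseq(ref, aEnd + da - flankK + 1L, aEnd + da)), "")
    right <- vapply(grid$db, function(db)
      as.character(subseq(ref, bStart + db, bStart + db + flankK - 1L)), "")
    cands <- DNAStringSet(paste0(left, right))
    pd <- PDict(cands)
    m <- vcountPDict(pd, rset)
    mrc <- vcountPDict(PDict(reverseComplement(cands)), rset)
    support <- rowSums((m + mrc) > 0L)
    best <- which(support == max(support))
    if (length(best) > 1L) {
      score <- abs(grid$da[best]) + abs(grid$db[best])
      best <- best[score == min(score)]
      best <- best[order(grid$da[best], grid$db[best])][1L]
    }
    endShift[i] <- grid$da[best]
    startShift[nxt[i]] <- grid$db[best]
  }
  ranges(seg) <- IRanges(start(seg) + startShift, end(seg) + endShift,
                         names = names(seg))
  CircleLayout(seg)
}

#' One-call reference-guided reconstruction
#'
#' Chains the pipeline downstream of segmentation: enumerate candidate
#' adjacencies from the duplication calls, score them against the reads,
#' resolve the circular layout, pin the boundaries with exact junction
#' support, and assemble the circle.
#'
#' @param calls duplication calls (named [GenomicRanges::GRanges]); deletions
#'   are ignored.
#' @param reference chromosome sequence.
#' @param reads long-read set or path.
#' @param params a [matchParams()] list used for candidate scoring.
#' @param minSupport,ambiguityFactor see [resolveLayout()].
#' @param refineWindow boundary search half-width for
#'   [refineLayoutWithReads()]; 0 disables read-based refinement.
#' @param flankK per-side flank length (default 25).
#' @return A list: `circle` ([ReconstructedCircle-class]), `layout`,
#'   `evidence` (scored candidate table), `junctions` (junctions of the final
#'   layout).
#' @export
reconstructCircle <- function(calls, reference, reads,
                              params = matchParams(), minSupport = 3L,
                              ambiguityFactor = 2, refineWindow = 40L,
                              flankK = 25L) {
  if (!is.null(calls$kind)) calls <- calls[calls$kind == "duplication"]
  if (is.null(names(calls)) && length(calls))
    names(calls) <- paste0("dup", seq_along(calls))
  cands <- enumerateCandidates(calls, reference, flankK = flankK)
  evidence <- scoreCandidates(cands, reads, params)
  layout <- resolveLayout(evidence, calls, minSupport = minSupport,
                          ambiguityFactor = ambiguityFactor)
  if (refineWindow > 0L && all(as.character(strand(layoutSegments(layout))) == "+"))
    layout <- refineLayoutWithReads(layout, reference, reads,
                                    window = refineWindow, flankK = flankK)
  circle <- assembleCircle(layout, reference)
  list(circle = circle, layout = layout, evidence = evidence,
       junctions = buildJunctions(layout, reference, flankK = flankK))
}

#' Write a reconstructed circle as FASTA
#'
#' The header carries the length and the layout string
#' (e.g. `dup1:+;dup2:+`).
#'
#' @param circle a [ReconstructedCircle-class].
#' @param path output FASTA.
#' @param name sequence name stem.
#' @return `path`, invisibly.
#' @export
writeCircleFasta <- function(circle, path, name = "circle") {
  s <- DNAStringSet(circleSequence(circle))
  names(s) <- sprintf("%s length=%d layout=%s", name, length(circle),
                      layoutString(circleLayout(circle)))
  writeXStringSet(s, path)
  invisible(path)
}
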