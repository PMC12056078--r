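#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
#' @importFrom stats rpois runif rlnorm setNames lm coef rbinom
NULL

#' Per-base sequencing depth along one contig
#'
#' A run-length encoded per-base depth vector tied to a contig name, as obtained
#' from `samtools depth`-style output, a bedGraph, or [simulateDepthTrack()].
#' Positions are 1-based; the track covers bases `1..length`.
#'
#' @slot contig single contig name.
#' @slot depth numeric [S4Vectors::Rle] of non-negative per-base depths.
#'
#' @seealso [DepthTrack()], [readDepthTrack()], [binAndNormalize()]
#' @exportClass DepthTrack
setClass("DepthTrack",
  representation(contig = "character", depth = "Rle"))

setValidity("DepthTrack", function(object) {
  msg <- NULL
  if (length(object@contig) != 1L || is.na(object@contig) || !nzchar(object@contig))
    msg <- c(msg, "'contig' must be a single non-empty string")
  v <- runValue(object@depth)
  if (!is.numeric(v))
    msg <- c(msg, "'depth' must be a numeric Rle")
  else if (length(v) && (anyNA(v) || any(v < 0)))
    msg <- c(msg, "depth values must be non-negative and non-missing")
  if (length(object@depth) < 1L)
    msg <- c(msg, "track must cover at least one base")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DepthTrack
#'
#' @param depth numeric vector or [S4Vectors::Rle] of per-base depths
#'   (position `i` = base `i`, 1-based).
#' @param contig contig name.
#' @return A [DepthTrack-class] object.
#' @examples
#' dt <- DepthTrack(rep(c(100, 220, 100), c(500, 300, 200)))
#' dt
#' @export
DepthTrack <- function(depth, contig = "chr") {
  if (!is(depth, "Rle")) depth <- Rle(as.numeric(depth))
  new("DepthTrack", contig = as.character(contig), depth = depth)
}

#' @describeIn DepthTrack-class number of bases covered by the track.
#' @param x,object a `DepthTrack`.
#' @export
setMethod("length", "DepthTrack", function(x) length(x@depth))

#' Accessors for DepthTrack
#'
#' `depthValues()` returns the per-base depth as an [S4Vectors::Rle];
#' `contigName()` the contig the track belongs to.
#'
#' @param x a [DepthTrack-class].
#' @return `depthValues`: numeric Rle; `contigName`: character scalar.
#' @export
depthValues <- function(x) {
  stopifnot(is(x, "DepthTrack"))
  x@depth
}

#' @rdname depthValues
#' @export
contigName <- function(x) {
  stopifnot(is(x, "DepthTrack"))
  x@contig
}

setMethod("show", "DepthTrack", function(object) {
  d <- object@depth
  cat("DepthTrack on '", object@contig, "': ", length(d), " bp, mean depth ",
      round(mean(d), 1), ", median ", round(median(d), 1), "\n", sep = "")
})

#' Circle-diagnostic junction sequences
#'
#' A set of 2k-mer junction sequences, each spanning an adjacency between two
#' oriented segment ends of a circular element: the last `flankK` bases
#' contributed by the left end followed by the first `flankK` bases contributed
#' by the right end. Such a sequence exists on the circle but (when specific)
#' nowhere on the source chromosome, making it diagnostic of circularisation.
#'
#' Extends [Biostrings::DNAStringSet]; element metadata columns record the
#' left/right segment names, orientations, and the genomic coordinate of each
#' flank's inner boundary.
#'
#' @slot flankK flank length k in bases (junction length is 2k).
#'
#' @seealso [buildJunctions()], [scanReads()], [checkSpecificity()]
#' @exportClass JunctionSet
setClass("JunctionSet",
  contains = "DNAStringSet",
  representation(flankK = "integer"))

setValidity("JunctionSet", function(object) {
  msg <- NULL
  k <- object@flankK
  if (length(k) != 1L || is.na(k) || k < 1L)
    msg <- c(msg, "'flankK' must be a single positive integer")
  else if (length(object) && any(width(object) != 2L * k))
    msg <- c(msg, sprintf("all junction sequences must have width 2*flankK = %d", 2L * k))
  if (length(object) && is.null(names(object)))
    msg <- c(msg, "junctions must be named")
  if (is.null(msg)) TRUE else msg
})

#' @rdname JunctionSet-class
#' @param x a `JunctionSet`.
#' @return `flankK()`: the per-side flank length k.
#' @export
flankK <- function(x) {
  stopifnot(is(x, "JunctionSet"))
  x@flankK
}

setMethod("show", "JunctionSet", function(object) {
  cat("JunctionSet of ", length(object), " junction(s), flankK = ",
      object@flankK, " (", 2L * object@flankK, " bp each)\n", sep = "")
  if (length(object)) {
    for (i in seq_along(object)) {
      cat("  ", names(object)[i], "  ", as.character(object[[i]]), "\n", sep = "")
    }
  }
})

#' Ordered layout of a circular element
#'
#' An ordered list of oriented chromosomal segments whose concatenation, read
#' circularly, is the circular element. Adjacencies are implied: the end of
#' element i joins the start of element i+1, and the last joins the first.
#'
#' @slot segments [GenomicRanges::GRanges] in layout order; `strand` gives each
#'   segment's orientation on the circle; names identify segments.
#'
#' @seealso [CircleLayout()], [resolveLayout()], [assembleCircle()]
#' @exportClass CircleLayout
setClass("CircleLayout", representation(segments = "GRanges"))

setValidity("CircleLayout", function(object) {
  msg <- NULL
  seg <- object@segments
  if (length(seg) < 1L)
    msg <- c(msg, "layout needs at least one segment")
  nm <- names(seg)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "segments must carry unique names (each segment appears once)")
  if (length(seg) && any(as.character(strand(seg)) == "*"))
    msg <- c(msg, "every segment must have an explicit orientation (+ or -)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CircleLayout
#'
#' @param segments a named [GenomicRanges::GRanges] in layout order with
#'   explicit strands.
#' @return A [CircleLayout-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(101, 301), c(200, 350)),
#'                              strand = c("+", "+"))
#' names(gr) <- c("dup1", "dup2")
#' CircleLayout(gr)
#' @export
CircleLayout <- function(segments) new("CircleLayout", segments = segments)

#' @rdname CircleLayout-class
#' @param x a `CircleLayout`.
#' @return `layoutSegments()`: the ordered, oriented GRanges.
#' @export
layoutSegments <- function(x) {
  stopifnot(is(x, "CircleLayout"))
  x@segments
}

#' @rdname CircleLayout-class
#' @export
layoutString <- function(x) {
  seg <- layoutSegments(x)
  paste(paste0(names(seg), ":", as.character(strand(seg))), collapse = ";")
}

#' @describeIn CircleLayout-class number of segments in the layout.
#' @export
setMethod("length", "CircleLayout", function(x) length(x@segments))

setMethod("show", "CircleLayout", function(object) {
  seg <- object@segments
  cat("CircleLayout: ", layoutString(object), " (", sum(width(seg)),
      " bp total)\n", sep = "")
})

#' A reconstructed circular element
#'
#' The assembled sequence of a circular element together with the segment
#' layout it was built from and the rotation applied to place the anchor at
#' position 1.
#'
#' @slot sequence assembled circular sequence as a [Biostrings::DNAString]
#'   (stored linearised at the chosen rotation).
#' @slot layout the [CircleLayout-class] it was assembled from.
#' @slot rotationAnchor 1-based position on the unrotated assembly now at
#'   position 1.
#'
#' @seealso [assembleCircle()], [rotateToAnchor()]
#' @exportClass ReconstructedCircle
setClass("ReconstructedCircle",
  representation(sequence = "DNAString", layout = "CircleLayout",
                 rotationAnchor = "integer"))

setValidity("ReconstructedCircle", function(object) {
  msg <- NULL
  expect <- sum(width(layoutSegments(object@layout)))
  if (length(object@sequence) != expect)
    msg <- c(msg, sprintf("sequence length (%d) must equal the sum of inclusive segment lengths (%d)",
                          length(object@sequence), expect))
  a <- object@rotationAnchor
  if (length(a) != 1L || is.na(a) || a < 1L || a > length(object@sequence))
    msg <- c(msg, "'rotationAnchor' must be a position on the circle")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ReconstructedCircle-class
#' @param x,object a `ReconstructedCircle`.
#' @return `circleSequence()`: the [Biostrings::DNAString];
#'   `circleLayout()`: the [CircleLayout-class]; `length()`: circle size in bp.
#' @export
circleSequence <- function(x) {
  stopifnot(is(x, "ReconstructedCircle"))
  x@sequence
}

#' @rdname ReconstructedCircle-class
#' @export
circleLayout <- function(x) {
  stopifnot(is(x, "ReconstructedCircle"))
  x@layout
}

#' @describeIn ReconstructedCircle-class circle length in bases.
#' @export
setMethod("length", "ReconstructedCircle", function(x) length(x@sequence))

setMethod("show", "ReconstructedCircle", function(object) {
  cat("ReconstructedCircle: ", length(object@sequence), " bp, layout ",
      layoutString(object@layout), ", rotation anchor ", object@rotationAnchor,
      "\n", sep = "")
})
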