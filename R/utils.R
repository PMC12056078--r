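# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Every stochastic operation takes an explicit
# seed; no global RNG state leaks between calls.
withSeed <- function(seed, expr) {
  if (length(seed) != 1L || is.na(seed) || seed != as.integer(seed))
    stop("'seed' must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sub-seed derived deterministically from a master seed, kept within 32-bit
# integer range.
deriveSeed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + i * 7919) %% .Machine$integer.max)
}

# Single-sequence DNAString from a DNAString/DNAStringSet/character/file-free
# input; errors on multi-sequence sets.
asDNAString <- function(x, what = "sequence") {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1L)
      stop(sprintf("'%s' must contain exactly one sequence", what))
    return(x[[1L]])
  }
  if (is.character(x) && length(x) == 1L) return(DNAString(x))
  stop(sprintf("cannot interpret '%s' as a single DNA sequence", what))
}

# 1-based inclusive subsequence of a circular molecule; `start` may exceed the
# molecule length (wraps), `len` may wrap past the end.
circularSubseq <- function(seq, start, len) {
  L <- length(seq)
  start <- ((start - 1L) %% L) + 1L
  if (len > L) stop("requested length exceeds the circle size")
  endpos <- start + len - 1L
  if (endpos <= L) {
    subseq(seq, start, endpos)
  } else {
    xscat(subseq(seq, start, L), subseq(seq, 1L, endpos - L))
  }
}

# condition helper: classed errors so callers/tests can distinguish failure modes
mtxStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
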