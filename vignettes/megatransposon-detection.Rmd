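---
title: "Detecting and quantifying a circular megatransposon from coverage and long reads"
author: "megatx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying a circular megatransposon from coverage and long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megatx)
library(GenomicRanges)
library(Biostrings)
```

## The problem

Some bacteria mobilise very large chromosomal regions as circular
extrachromosomal elements. In carboxydotrophic acetogens, a ~86 kb circular
"megatransposon" carrying the Wood–Ljungdahl pathway locus appears when cells
grow on carbon monoxide: two chromosomal segments, tens of kilobases each and
separated by a short gap, are excised and joined into one circle. Three
signals betray such an element in sequencing data:

1. **Coverage**: the duplicated segments show elevated short-read depth — a
   copy ratio near 2 for a population carrying the chromosome plus one
   extrachromosomal copy (the observed signal was ~2.2, i.e. 1765× and 1739×
   against an 802× genome median).
2. **Junctions**: the circle contains two adjacencies that exist nowhere on
   the chromosome. A *junction sequence* is a 2k-mer (k = 25 by default, so
   50 bp) made of the last k bases contributed by one segment end and the
   first k bases of the next. Long reads spanning a junction prove the circle
   physically; counting them, normalised per gigabase of sequencing, proxies
   its abundance across conditions.
3. **Layout**: with junction support for each adjacency, the circle can be
   reconstructed reference-guided — ordering and orienting the called
   segments into a single cycle and concatenating their sequences — without
   de novo assembly.

megatx implements this inference chain, a seeded simulator that generates
data with known truth for every stage, and the chemostat/batch physiology
arithmetic (N₂-referenced gas rates, yields, stoichiometric ratios, growth
rates, carbon balance) used to characterise the strains that carry the
element.

## Coverage segmentation

`binAndNormalize()` bins per-base depth (default 1 kb bins) and divides bin
means by the genome-wide **median** bin depth. The median, not the mean, sets
the baseline deliberately: the duplications of interest span several percent
of a small genome, enough to drag a mean-normalised baseline upward and bias
every ratio. `callSegments()` then takes maximal runs of bins at or above the
duplication threshold (or at/below the deletion threshold), merges runs
separated by at most `maxGapBins` non-qualifying bins, and discards calls
shorter than a kind-specific minimum.

Parameters and rationale:

* `dupThreshold = 1.75` — halfway between single copy (1.0) and the expected
  one-extra-copy signal (~2); comfortably below the observed 2.2 while
  rejecting noise around 1.
* `delThreshold = 0.25` — a homozygous deletion has expected ratio 0; 0.25
  tolerates mismapping and bin-edge effects.
* `minDupLength = 10000` bases, `minDelLength = 1000` bases — the target
  duplications are tens of kb, the deletion of interest 2.4 kb.
* `maxGapBins = 5` — bridges isolated noisy bins without merging genuinely
  separate events (the two real duplications are 8.3 kb apart and must remain
  two calls at 1 kb bins).

Bin boundaries quantise call coordinates, so `refineBoundaries()` sharpens
each boundary on the per-base track: within ±`refineWindow` (default 2000)
of a boundary it picks the base maximising the absolute contrast between the
mean depth over the `refineWindow/2` bases before and after. Ties break
toward the unrefined boundary and then toward the smaller coordinate; the
segment end is refined at its first-base-after position and converted back,
so both boundaries use the same objective. At the depth scale of the study
(802× vs 1765×) this lands within a few bases of the true step.

Copy ratios are reported as the **median** of in-segment bin ratios to two
decimals. Reports always carry both length conventions — the inclusive
length `end − start + 1` and the span `end − start` — because published
coordinate arithmetic uses the span while circle sizes sum inclusive
lengths; for the published coordinates these are 60,102/60,101 and
25,709/25,708, and the circle length 60,102 + 25,709 = 85,811.

```{r depthdemo}
ev <- GRanges("chr", IRanges::IRanges(c(20001, 48001), c(40000, 58000)),
              copyRatio = 1765 / 802)
dt <- simulateDepthTrack(100000, ev, meanDepth = 802, seed = 7)
bins <- binAndNormalize(dt, 1000)
calls <- refineBoundaries(callSegments(bins, segmentationParams()), dt)
segmentReport(calls)
```

## Junction construction and scanning

`buildJunctions()` derives one junction per adjacency of a circular layout;
`checkSpecificity()` verifies the diagnostic property — neither the junction
nor its reverse complement occurs on the reference (with an optional
origin-spanning window for circular references). `scanReads()` counts, for
each junction, the **reads** containing it (a read counts once per junction
however many times the junction occurs in it), semi-globally: the junction
must align end-to-end against a read substring within `maxEdits` edit
operations. Counts are normalised by the total bases of the read set as
provided — no trimming — and reported as reads per Gb.

The default `maxEdits = 0` mirrors selection of raw reads by exact 50-mer
content. With i.i.d. per-base error rate *e*, the chance that a read copy of
a 50-mer is error-free is (1 − e)⁵⁰ — about 36% at e = 2% — so a noisy-read
preset of `maxEdits = 3` is provided; matching is exact Levenshtein (the
Biostrings with-indels matcher), and the test suite pins it against an
independent dynamic-programming oracle. `maxEdits` is capped at k/2 so a
junction can never be explained by one flank alone.

```{r junctiondemo}
g <- generateGenome(60000, 0.45, seed = 11)
sc <- buildScenario(g, c(10001, 22000), c(28001, 39000))
sc$junctions
src <- list(chr = list(seq = g[[1]], circular = FALSE, weight = 1),
            circle = list(seq = circleSequence(sc$circle), circular = TRUE,
                          weight = 2))
rd <- simulateLongReads(src, readSimParams(totalBases = 3e5,
                                           meanLog = log(2000), sdLog = 0.3,
                                           subRate = 0, insRate = 0,
                                           delRate = 0), seed = 12)
scanReads(rd, sc$junctions)$table
```

## Circle reconstruction

Reconstruction is reference-guided, not de novo: the segments come from the
depth caller, their order and orientation from junction evidence.
`enumerateCandidates()` builds the junction for every ordered pair of
oriented segment ends (self-joins included), collapses reverse-complement
duplicates (two segments give 10 classes, one segment 3), and flags
candidates whose sequence already occurs on the reference — those are
reference adjacencies, not circle evidence. `scoreCandidates()` counts
supporting reads in one pass; `resolveLayout()` greedily accepts the
best-supported candidate whose segment ends are both free, requiring
`minSupport` reads (default 3), and aborts with an `ambiguous_layout` error
whenever a rejected competitor sharing an end scores within
`ambiguityFactor` (default 2) of an accepted candidate. The accepted
adjacencies must close a single Hamiltonian cycle over the segments —
checked exactly, since segment counts are tiny — otherwise an
`incomplete_circle` error carries the evidence table for inspection.

Because a 50-mer junction is destroyed by even a one-base boundary error,
`refineLayoutWithReads()` pins each adjacency to base resolution before
assembly: all junction 2k-mers for boundary offsets within ±40 bases are
matched exactly against the reads in one dictionary pass, and the
offset pair with maximal support wins (ties toward the depth-refined
boundary, then the smaller coordinate). `assembleCircle()` concatenates the
oriented segment sequences — the length always equals the sum of inclusive
segment lengths — and `rotateToAnchor()` re-linearises the circle at any
position; the default anchor is the start of the first segment, since
rotating to a named feature (the IS element of the first duplication, in the
motivating case) requires annotation this package does not do.

```{r reconstructdemo}
res <- reconstructCircle(sc$segments, g, rd, params = matchParams(0))
res$circle
identical(as.character(circleSequence(res$circle)),
          as.character(circleSequence(sc$circle)))
```

## The simulator: what it emulates, what it does not

The simulator generates (i) an i.i.d. random genome at a target GC content,
(ii) a two-segment forward-forward circle scenario with its truth junctions,
(iii) per-base depth drawn Poisson(meanDepth × local copy ratio) — depth is
simulated directly rather than via read alignment so segmentation is testable
without an aligner; a short-read emitter exists for users who want to run
one — and (iv) long reads with truncated-lognormal lengths (default median
5,697 bases, matching the raw-read scale of the motivating dataset, capped at
50 kb) and i.i.d. substitution/insertion/deletion errors (defaults
0.02/0.015/0.02). Sources are sampled proportionally to weight × length,
start positions are uniform with wrap-around on circular molecules, and reads
running off a linear 3′ end are truncated there, so error-free reads are
always exact substrings of their source. Every operation takes an explicit
seed and restores the caller's RNG state; identical inputs give
byte-identical FASTA/FASTQ/track outputs.

Deliberate simplifications: no homopolymer-aware or quality-dependent error
model (qualities are a uniform dummy 'I'), no chimeric reads, no GC or
mappability bias in depth, and the circle copy weight is a free parameter —
the true per-cell copy number under CO is not established. Passing tests
therefore demonstrate correctness of the inference machinery under idealised
noise, not robustness to every artefact of real nanopore data.

The closed-form check used in the tests: with B bases of fixed-length-L
error-free reads from a circle of length C, each junction is fully contained
in a read with probability (L − 49)/C per read, so the expected
junction-bearing read count is (B/L)·(L − 49)/C. Reads per Gb is
proportional to the circle copy weight only while the circle contributes a
small fraction of the library — the regime of an ~86 kb element against a
2.4 Mb chromosome, and the geometry the linearity test uses; at high weights
the rate saturates because the circle inflates the denominator too.

## Physiology

For gas fermentations the off-gas flow changes as gas is consumed, so
specific rates use N₂ as an internal standard: outlet molar flow equals
inlet flow × y(N₂,in)/y(N₂,out), and q_i = (inFlow·y_i,in −
outFlow·y_i,out)/(V·X), positive for uptake and negative for production —
the table convention of the motivating study (e.g. q_H2 < 0 on CO is the
biological water-gas shift). N₂'s own rate is zero by construction and the
result is invariant to consistent rescaling of either composition.

Steady-state derived quantities, with rounding conventions chosen to match
how such tables are printed: q_Ace = 1000·D·c_Ace/(M_acetate·X) (feed
acetate assumed zero — chemically defined medium), Y_Ace/Biomass =
c_Ace/(M_acetate·X) to 2 decimals, Y_Biomass/S = 1000·D/q_S in g mol⁻¹,
substrate:acetate ratios to 1 decimal, and the carbon balance
100 × (production C + acetate C + biomass C)/(uptake C) with biomass carbon
converted through a configurable `biomassGPerCmol` (default 25.0 g per
C-mol, a standard CH₁.₈O₀.₅N₀.₂-type composition). The biomass elemental
composition behind published balances is typically unstated, so carbon
balances are checked against tolerance bands, never digit-for-digit.
A second caveat the tests encode explicitly: published tables average
per-replicate ratios, while recomputation from column means gives the ratio
of means — for the motivating Table these differ in the last printed digit
(e.g. a recomputed q_Ace of 15.1 against a printed 14.6 ± 0.5, or an
acetate yield of 0.345 that rounds to 0.35 against a printed 0.34 ± 0.03),
so agreement is asserted within one printed standard deviation.

Growth rates come from a least-squares fit of ln(OD) against time inside the
user-chosen exponential window, with T_d = ln 2/µ to one decimal (µ = 0.25
h⁻¹ gives 2.8 h; 0.12 h⁻¹ gives 5.8 h).

```{r physiodemo}
steadyStateReport(data.frame(
  strain = "CO-1", gas = "CO", D = 0.10, biomass = 0.24, acetate = 2.18,
  qH2 = -16.7, qCO2 = -47.0, qCO = 80.0, substrate = "CO"))
```

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout, matching how bacterial
  genome coordinates are printed; bedGraph I/O converts to and from 0-based
  half-open at the file boundary.
* **Problem sizes in tests**: the chromosome is scaled to 60–200 kb and read
  sets to 0.2–1.5 Mb per seed. The inference problem is scale-free — the
  depth caller sees ratios, the junction scanner sees local 50-mers — so
  these sizes exercise the same code paths as a 2.4 Mb genome while keeping
  the full suite fast; the genome-scale coordinate arithmetic is additionally
  checked directly on the published positions.
* **Ties and degeneracies**: boundary-refinement ties break toward the
  unrefined boundary; all-zero depth tracks and empty read sets raise typed
  errors (`degenerate_input`) or return flagged empty reports rather than
  NaNs; a track shorter than one bin is a single bin of ratio 1.
* **Error handling** uses classed conditions (`invalid_parameter`,
  `invalid_interval`, `invalid_input`, `ambiguous_layout`,
  `incomplete_circle`) so callers can branch on failure modes; the layout
  errors carry the full evidence table.

## Limitations

Reconstruction assumes the element is a single circle built from the called
segments: multi-circle mixtures, inversions internal to a segment, and
foldback-only structures are detected as ambiguity/incompleteness errors,
not resolved. Junction quantification compares conditions through a
normalised rate, not an absolute copy number per cell. The physiology module
computes steady-state arithmetic; it does not fit raw online-GC time series
or model ATP yields.
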