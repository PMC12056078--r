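Package: megatx
Title: Discovery, Quantification and Reconstruction of Circular Megatransposons
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-guided detection and reconstruction of large circular
    extrachromosomal transposable elements in bacterial genomes, as observed in
    carboxydotrophic acetogens: copy-number segmentation of short-read depth
    tracks, construction and specificity checking of circle-diagnostic junction
    sequences (2k-mers spanning segment adjacencies), exact and edit-distance
    scanning of long reads with depth-normalised quantification (reads per Gb),
    and assembly of the circular element from called segments plus junction
    evidence. A seeded simulator generates genomes, circles, depth tracks and
    error-bearing long reads with known truth. Companion routines compute
    gas-fermentation physiology for chemostat and batch cultures: N2-referenced
    gas uptake/production rates, specific rates, yields, substrate:product
    stoichiometry, growth rate and carbon balance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralVariation, CopyNumberVariation, Sequencing, Coverage
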