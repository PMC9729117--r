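Package: LoopKinetics
Title: Chromatin Loop Analysis and Transcription Factor Binding Kinetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking 3D genome structure to transcription and
    transcription-factor dynamics. Provides a binned contact-matrix
    container with iterative-correction balancing, distance
    (observed/expected) normalization and contact-decay statistics with
    ligation-orientation parsing; insulation-score TAD boundary calling,
    compartment eigenvectors and saddle compartment strength; loop
    strength scoring, aggregate peak analysis, chromatin-state anchor
    classification (cohesin, enhancer-promoter, promoter-promoter,
    polycomb), differential loop calls across protein-depletion
    conditions and TAD-boundary-crossing annotation; loop-expression
    association (LOESS strength-expression curves, metagene profiles,
    differential-gene enrichment); and single-molecule kinetics:
    diffusion-state mixture fits of single-particle-tracking jump
    lengths, residence times from slow-tracking survival curves and
    reaction-dominant FRAP, and target-search time inference. A
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: HiC, Epigenetics, SingleCell, Transcription, Software
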