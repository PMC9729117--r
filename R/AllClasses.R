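#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width mcols mcols<- findOverlaps countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' The 12-state chromatin vocabulary
#'
#' Chromatin-state labels used to annotate loop anchors, following the
#' standard mESC ChromHMM segmentation: CTCF/insulator, active promoter,
#' three enhancer strengths plus a promoter/enhancer mix, bivalent
#' promoter, gene body, polycomb repressor, intergenic, heterochromatin
#' and repeats.
#'
#' @return Character vector of the 12 state names.
#' @export
chromatinStates <- function() {
  c("CTCF/insulator", "active promoter", "strong enhancer",
    "medium enhancer", "weak enhancer", "promoter/enhancer mix",
    "bivalent promoter", "gene body", "polycomb repressor",
    "intergenic", "heterochromatin", "repeats")
}

## states collapsed to the anchor-label alphabet {C, P, E, B}
.stateLabelMap <- c(
  "CTCF/insulator" = "C",
  "active promoter" = "P",
  "strong enhancer" = "E",
  "medium enhancer" = "E",
  "weak enhancer" = "E",
  "promoter/enhancer mix" = "E",
  "bivalent promoter" = "B",
  "polycomb repressor" = "B")

#' BinnedContactMatrix: symmetric binned contact counts
#'
#' Container for a single-chromosome binned contact map: a symmetric
#' nonnegative count matrix with equal-width, contiguous, 0-based
#' half-open bins, per-bin balancing weights (NA until balancing) and a
#' blocked-bin mask for low-coverage/unmappable bins.
#'
#' @slot chrom Chromosome name.
#' @slot binSize Bin width in bp.
#' @slot counts Symmetric matrix (raw counts, balanced signal or O/E,
#'   see \code{normalization}).
#' @slot weights Per-bin balancing weights; NA for masked bins or before
#'   balancing.
#' @slot mask Logical, TRUE for blocked bins.
#' @slot normalization One of "raw", "balanced", "oe".
#' @export
setClass("BinnedContactMatrix",
  slots = c(chrom = "character", binSize = "numeric", counts = "matrix",
            weights = "numeric", mask = "logical",
            normalization = "character"))

setValidity("BinnedContactMatrix", function(object) {
  msg <- NULL
  n <- nrow(object@counts)
  if (ncol(object@counts) != n)
    msg <- c(msg, "counts must be square")
  if (length(object@mask) != n || length(object@weights) != n)
    msg <- c(msg, "mask and weights must have one entry per bin")
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be nonnegative")
  if (n > 0 && !isTRUE(all.equal(object@counts, t(object@counts),
                                 check.attributes = FALSE)))
    msg <- c(msg, "counts must be symmetric")
  if (!object@normalization %in% c("raw", "balanced", "oe"))
    msg <- c(msg, "normalization must be raw, balanced or oe")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BinnedContactMatrix
#'
#' @param counts Symmetric count matrix.
#' @param chrom Chromosome name.
#' @param binSize Bin width (bp).
#' @param weights Optional balancing weights (default NA).
#' @param mask Optional blocked-bin flags (default all FALSE).
#' @param normalization "raw", "balanced" or "oe".
#' @return A \linkS4class{BinnedContactMatrix}.
#' @export
BinnedContactMatrix <- function(counts, chrom = "chrS", binSize,
                                weights = rep(NA_real_, nrow(counts)),
                                mask = rep(FALSE, nrow(counts)),
                                normalization = "raw") {
  new("BinnedContactMatrix", chrom = chrom, binSize = as.numeric(binSize),
      counts = counts, weights = weights, mask = mask,
      normalization = normalization)
}

#' @describeIn BinnedContactMatrix number of bins
#' @param x,object A BinnedContactMatrix.
#' @export
setMethod("length", "BinnedContactMatrix", function(x) nrow(x@counts))

#' Accessors for BinnedContactMatrix
#'
#' \code{contactCounts} returns the stored matrix, \code{binSize} the bin
#' width, \code{balancingWeights} the per-bin weights, \code{binMask} the
#' blocked-bin flags and \code{bins} the bin intervals as a
#' \code{GRanges}.
#'
#' @param x A \linkS4class{BinnedContactMatrix}.
#' @return See individual descriptions.
#' @export
contactCounts <- function(x) x@counts

#' @rdname contactCounts
#' @export
binSize <- function(x) x@binSize

#' @rdname contactCounts
#' @export
balancingWeights <- function(x) x@weights

#' @rdname contactCounts
#' @export
binMask <- function(x) x@mask

#' @rdname contactCounts
#' @export
bins <- function(x) {
  n <- length(x)
  GRanges(x@chrom, IRanges(start = (seq_len(n) - 1L) * x@binSize + 1L,
                           width = x@binSize))
}

setMethod("show", "BinnedContactMatrix", function(object) {
  cat("BinnedContactMatrix:", object@chrom, "\n")
  cat("  ", length(object), "bins of", object@binSize, "bp;",
      sum(object@mask), "masked\n")
  cat("  normalization:", object@normalization)
  if (object@normalization == "raw")
    cat("; total (upper tri + diag):",
        sum(object@counts[upper.tri(object@counts, diag = TRUE)]))
  cat("\n")
})

#' LoopSet: anchor pairs with class labels and per-condition scores
#'
#' A set of loops (focal contact enrichments). Each loop joins two
#' anchors (0-based half-open intervals on one chromosome), carries a
#' class label (cohesin, EP, PP, polycomb, other) and a table of
#' per-condition enrichment scores.
#'
#' @slot anchor1,anchor2 \code{GRanges} of equal length; anchor1 is
#'   upstream of anchor2.
#' @slot loopClass Character vector of class labels.
#' @slot scores data.frame of per-condition scores (may have 0 columns).
#' @export
setClass("LoopSet",
  slots = c(anchor1 = "GRanges", anchor2 = "GRanges",
            loopClass = "character", scores = "data.frame"))

setValidity("LoopSet", function(object) {
  n <- length(object@anchor1)
  msg <- NULL
  if (length(object@anchor2) != n || length(object@loopClass) != n)
    return("anchor1, anchor2 and loopClass lengths differ")
  if (nrow(object@scores) != n && nrow(object@scores) != 0)
    msg <- c(msg, "scores must have one row per loop")
  if (n > 0) {
    m1 <- (start(object@anchor1) + end(object@anchor1)) / 2
    m2 <- (start(object@anchor2) + end(object@anchor2)) / 2
    if (any(m1 > m2))
      msg <- c(msg, "anchor1 must lie upstream of anchor2")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a LoopSet
#'
#' @param anchor1,anchor2 GRanges of anchors (anchor1 upstream).
#' @param loopClass Optional class labels (default "other").
#' @param scores Optional data.frame of per-condition scores.
#' @return A \linkS4class{LoopSet}.
#' @export
LoopSet <- function(anchor1, anchor2,
                    loopClass = rep("other", length(anchor1)),
                    scores = data.frame(row.names = seq_along(anchor1))) {
  new("LoopSet", anchor1 = anchor1, anchor2 = anchor2,
      loopClass = loopClass, scores = scores)
}

#' @describeIn LoopSet number of loops
#' @param x,object A LoopSet.
#' @export
setMethod("length", "LoopSet", function(x) length(x@anchor1))

#' LoopSet accessors
#'
#' \code{anchorOne}/\code{anchorTwo} return the anchor \code{GRanges},
#' \code{loopClass} the class labels, \code{loopScores} the score table
#' and \code{loopDistance} the midpoint separation in bp.
#'
#' @param x A \linkS4class{LoopSet}.
#' @param value Replacement value.
#' @return See individual descriptions.
#' @export
anchorOne <- function(x) x@anchor1

#' @rdname anchorOne
#' @export
anchorTwo <- function(x) x@anchor2

#' @rdname anchorOne
#' @export
loopClass <- function(x) x@loopClass

#' @rdname anchorOne
#' @export
`loopClass<-` <- function(x, value) {
  x@loopClass <- value
  validObject(x)
  x
}

#' @rdname anchorOne
#' @export
loopScores <- function(x) x@scores

#' @rdname anchorOne
#' @export
`loopScores<-` <- function(x, value) {
  x@scores <- value
  validObject(x)
  x
}

#' @rdname anchorOne
#' @export
loopDistance <- function(x) {
  (start(x@anchor2) + end(x@anchor2)) / 2 -
    (start(x@anchor1) + end(x@anchor1)) / 2
}

#' @rdname anchorOne
#' @param i Index.
#' @export
setMethod("[", "LoopSet", function(x, i) {
  sc <- x@scores
  if (nrow(sc) > 0) sc <- sc[i, , drop = FALSE]
  new("LoopSet", anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
      loopClass = x@loopClass[i], scores = sc)
})

setMethod("show", "LoopSet", function(object) {
  cat("LoopSet with", length(object), "loops\n")
  if (length(object)) {
    cat("  classes:", paste(names(table(object@loopClass)),
        table(object@loopClass), sep = ":", collapse = " "), "\n")
    if (ncol(object@scores))
      cat("  score conditions:", paste(colnames(object@scores),
          collapse = ", "), "\n")
  }
})

#' ChromatinStateTrack: 12-state segmentation plus anchor peak sets
#'
#' Genomic segmentation into the 12-state chromatin vocabulary
#' (\code{\link{chromatinStates}}) together with the CTCF and cohesin
#' ChIP peak sets used to label loop anchors as structural.
#'
#' @slot states \code{GRanges} with an mcols \code{state} column drawn
#'   from the 12-state vocabulary; segments may overlap (multi-label).
#' @slot ctcfPeaks,cohesinPeaks Peak \code{GRanges}.
#' @export
setClass("ChromatinStateTrack",
  slots = c(states = "GRanges", ctcfPeaks = "GRanges",
            cohesinPeaks = "GRanges"))

setValidity("ChromatinStateTrack", function(object) {
  st <- mcols(object@states)$state
  if (length(object@states) == 0) return(TRUE)
  if (is.null(st))
    return("states GRanges needs a 'state' metadata column")
  if (!all(st %in% chromatinStates()))
    return("state labels must be drawn from the 12-state vocabulary")
  TRUE
})

#' Construct a ChromatinStateTrack
#'
#' @param states GRanges with a \code{state} mcols column.
#' @param ctcfPeaks,cohesinPeaks Peak GRanges (default empty).
#' @return A \linkS4class{ChromatinStateTrack}.
#' @export
ChromatinStateTrack <- function(states, ctcfPeaks = GRanges(),
                                cohesinPeaks = GRanges()) {
  new("ChromatinStateTrack", states = states, ctcfPeaks = ctcfPeaks,
      cohesinPeaks = cohesinPeaks)
}

#' ChromatinStateTrack accessors
#' @param x A \linkS4class{ChromatinStateTrack}.
#' @return The corresponding GRanges.
#' @export
stateSegments <- function(x) x@states

#' @rdname stateSegments
#' @export
ctcfPeaks <- function(x) x@ctcfPeaks

#' @rdname stateSegments
#' @export
cohesinPeaks <- function(x) x@cohesinPeaks

setMethod("show", "ChromatinStateTrack", function(object) {
  cat("ChromatinStateTrack:", length(object@states), "segments,",
      length(object@ctcfPeaks), "CTCF peaks,",
      length(object@cohesinPeaks), "cohesin peaks\n")
})

#' TrajectorySet: single-particle tracking localizations
#'
#' Localization time series from single-particle tracking: one row per
#' localization with trajectory id, frame, time (s) and x/y position
#' (micrometres), plus the acquisition frame interval and the nominal
#' localization error.
#'
#' @slot tracks data.frame with columns trajectory_id, frame, t_s, x_um,
#'   y_um.
#' @slot frameInterval Frame interval in seconds.
#' @slot sigmaLoc Nominal localization error (um, per axis).
#' @slot halfDepth Axial detection half-depth (um); Inf when the axial
#'   detection geometry is unknown.
#' @export
setClass("TrajectorySet",
  slots = c(tracks = "data.frame", frameInterval = "numeric",
            sigmaLoc = "numeric", halfDepth = "numeric"))

setValidity("TrajectorySet", function(object) {
  need <- c("trajectory_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% colnames(object@tracks)))
    return(paste("tracks must have columns",
                 paste(need, collapse = ", ")))
  if (object@frameInterval <= 0) return("frameInterval must be positive")
  d <- object@tracks
  if (nrow(d) > 1) {
    ord <- order(d$trajectory_id, d$frame)
    d <- d[ord, ]
    same <- d$trajectory_id[-1] == d$trajectory_id[-nrow(d)]
    if (any(same & diff(d$frame) <= 0))
      return("frames must be strictly increasing within a trajectory")
  }
  TRUE
})

#' Construct a TrajectorySet
#'
#' @param tracks data.frame (trajectory_id, frame, t_s, x_um, y_um).
#' @param frameInterval Frame interval (s).
#' @param sigmaLoc Localization error (um).
#' @param halfDepth Axial detection half-depth (um); Inf if unknown.
#' @return A \linkS4class{TrajectorySet}.
#' @export
TrajectorySet <- function(tracks, frameInterval, sigmaLoc = NA_real_,
                          halfDepth = Inf) {
  new("TrajectorySet", tracks = tracks,
      frameInterval = as.numeric(frameInterval),
      sigmaLoc = as.numeric(sigmaLoc), halfDepth = as.numeric(halfDepth))
}

#' @describeIn TrajectorySet number of trajectories
#' @param x,object A TrajectorySet.
#' @export
setMethod("length", "TrajectorySet",
          function(x) length(unique(x@tracks$trajectory_id)))

#' TrajectorySet accessors
#' @param x A \linkS4class{TrajectorySet}.
#' @return See descriptions.
#' @export
trackTable <- function(x) x@tracks

#' @rdname trackTable
#' @export
frameInterval <- function(x) x@frameInterval

#' @rdname trackTable
#' @export
sigmaLoc <- function(x) x@sigmaLoc

setMethod("show", "TrajectorySet", function(object) {
  cat("TrajectorySet:", length(object), "trajectories,",
      nrow(object@tracks), "localizations\n")
  cat("  frame interval", object@frameInterval, "s; sigma_loc",
      object@sigmaLoc, "um\n")
})

#' StateMixtureFit: diffusion-state mixture fit result
#'
#' Result of the maximum-likelihood jump-length mixture fit: state
#' fractions and diffusion coefficients, plus fractions binned into the
#' bound (D < 0.1), slow (0.1-2) and fast (> 2 um^2/s) classes.
#'
#' @slot fractions,D Per-component occupancies and diffusion
#'   coefficients (um^2/s).
#' @slot sigmaLoc Localization error used/estimated (um).
#' @slot logLik Maximized log-likelihood.
#' @slot nJumps Number of jumps used.
#' @slot binned Named numeric: bound, slow, fast fractions.
#' @slot defocalizationCorrected Logical.
#' @export
setClass("StateMixtureFit",
  slots = c(fractions = "numeric", D = "numeric", sigmaLoc = "numeric",
            logLik = "numeric", nJumps = "integer", binned = "numeric",
            defocalizationCorrected = "logical"))

#' @describeIn StateMixtureFit bound-state fraction (D < 0.1 um^2/s)
#' @param x,object A StateMixtureFit.
#' @export
boundFraction <- function(x) unname(x@binned["bound"])

#' @rdname boundFraction
#' @export
stateFractions <- function(x) x@fractions

#' @rdname boundFraction
#' @export
diffusionCoefficients <- function(x) x@D

setMethod("show", "StateMixtureFit", function(object) {
  cat("StateMixtureFit (", length(object@fractions), " states, ",
      object@nJumps, " jumps)\n", sep = "")
  cat("  D (um^2/s):", signif(object@D, 3), "\n")
  cat("  fractions :", round(object@fractions, 3), "\n")
  cat("  bound/slow/fast:", round(object@binned, 3), "\n")
})

#' SurvivalFit: slow-SPT survival-curve fit
#'
#' Exponential(-mixture) fit of binding durations with photobleaching
#' correction, yielding corrected dissociation rates and residence
#' times.
#'
#' @slot rates Corrected dissociation rates (1/s).
#' @slot weights Mixture weights (sum 1).
#' @slot kB Photobleaching rate per frame used for correction (NA if
#'   extrapolated or uncorrected).
#' @slot apparentRates Apparent rates per exposure (1/s).
#' @slot exposures Exposure times (s).
#' @slot residenceTimes 1/rates (s).
#' @slot corrected TRUE if photobleaching-corrected.
#' @export
setClass("SurvivalFit",
  slots = c(rates = "numeric", weights = "numeric", kB = "numeric",
            apparentRates = "numeric", exposures = "numeric",
            residenceTimes = "numeric", corrected = "logical"))

#' @describeIn SurvivalFit corrected residence times (s)
#' @param x,object A SurvivalFit or FRAPFit.
#' @export
residenceTimes <- function(x) x@residenceTimes

setMethod("show", "SurvivalFit", function(object) {
  cat("SurvivalFit:", length(object@rates), "component(s);",
      if (object@corrected) "photobleaching-corrected" else
        "apparent (uncorrected)", "\n")
  cat("  k_off (1/s):", signif(object@rates, 4),
      " residence (s):", signif(object@residenceTimes, 4), "\n")
})

#' FRAPFit: reaction-dominant FRAP recovery fit
#'
#' @slot model "one-binding-state" or "two-binding-state".
#' @slot rates Dissociation rates (1/s).
#' @slot amplitudes Recovery amplitudes per component.
#' @slot plateau Fitted plateau (1 - non-recovering fraction).
#' @slot residSE Residual standard error.
#' @slot residenceTimes 1/rates (s).
#' @export
setClass("FRAPFit",
  slots = c(model = "character", rates = "numeric",
            amplitudes = "numeric", plateau = "numeric",
            residSE = "numeric", residenceTimes = "numeric"))

setMethod("show", "FRAPFit", function(object) {
  cat("FRAPFit (", object@model, ")\n", sep = "")
  cat("  k_off (1/s):", signif(object@rates, 4),
      " residence (s):", signif(object@residenceTimes, 4), "\n")
})

#' SearchKinetics: target-search parameters
#'
#' Bound fraction and residence time combined into the pseudo
#' association rate k*_on = k_off * F_bound / (1 - F_bound) and the
#' target-search time tau_search = 1/k*_on.
#'
#' @slot fBound Bound fraction in (0, 1).
#' @slot tauRes Residence time (s).
#' @slot kOn Pseudo-association rate (1/s).
#' @slot tauSearch Search time (s).
#' @export
setClass("SearchKinetics",
  slots = c(fBound = "numeric", tauRes = "numeric", kOn = "numeric",
            tauSearch = "numeric"))

#' @describeIn SearchKinetics search time in seconds
#' @param x,object A SearchKinetics.
#' @export
searchTime <- function(x) x@tauSearch

#' @rdname searchTime
#' @export
pseudoOnRate <- function(x) x@kOn

setMethod("show", "SearchKinetics", function(object) {
  cat("SearchKinetics: F_bound =", round(object@fBound, 3),
      " tau_res =", signif(object@tauRes, 4), "s\n")
  cat("  k*_on =", signif(object@kOn, 4), "1/s  tau_search =",
      signif(object@tauSearch, 4), "s\n")
})
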