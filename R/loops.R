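## Loop analysis: strength scoring, APA pileups, anchor-state
## classification, differential calls and TAD-boundary-crossing
## annotation.

## bin index (1-based) of an anchor midpoint
.anchorBin <- function(anchor, binSize) {
  floor(((start(anchor) - 1 + end(anchor)) / 2) / binSize) + 1L
}

#' Loop strength score
#'
#' For each loop pixel (i, j) on the O/E matrix, the score is the mean
#' O/E over the centre 3x3 pixels divided by the mean O/E over the
#' four 3x3 corner background boxes of the (2w+1)^2 window (corners at
#' offsets +/- w). Loops whose window is clipped by the matrix edge or
#' reaches the diagonal are flagged undefined (NA).
#'
#' @param x An O/E \linkS4class{BinnedContactMatrix} (2-kb bins in the
#'   reference analysis).
#' @param loops A \linkS4class{LoopSet}.
#' @param w Corner offset in bins (default 5).
#' @return Numeric score per loop (NA where undefined).
#' @export
scoreLoops <- function(x, loops, w = 5L) {
  M <- x@counts
  n <- nrow(M)
  bs <- x@binSize
  i <- .anchorBin(anchorOne(loops), bs)
  j <- .anchorBin(anchorTwo(loops), bs)
  vapply(seq_along(i), function(k) {
    .scorePixel(M, n, i[k], j[k], w)
  }, 1)
}

.scorePixel <- function(M, n, i, j, w) {
  if (i - w < 1 || j + w > n || i + w > n || j - w < 1)
    return(NA_real_)  # clipped by matrix edge
  if (j - i <= 2 * w + 2) return(NA_real_)  # window reaches diagonal
  box <- function(ci, cj) M[(ci - 1):(ci + 1), (cj - 1):(cj + 1)]
  centre <- mean(box(i, j), na.rm = TRUE)
  corners <- c(box(i - w, j - w), box(i - w, j + w),
               box(i + w, j - w), box(i + w, j + w))
  bg <- mean(corners, na.rm = TRUE)
  if (!is.finite(centre) || !is.finite(bg) || bg == 0)
    return(NA_real_)
  centre / bg
}

#' Aggregate peak analysis (APA)
#'
#' Element-wise mean of the (2w+1)x(2w+1) O/E windows centred on each
#' scoreable loop pixel, with the centre enrichment ratio (centre 3x3
#' mean over the four-corner background mean of the averaged window).
#'
#' @inheritParams scoreLoops
#' @return List: \code{apa} ((2w+1)^2 matrix), \code{centerRatio},
#'   \code{n} contributing loops.
#' @export
apa <- function(x, loops, w = 5L) {
  M <- x@counts
  n <- nrow(M)
  bs <- x@binSize
  i <- .anchorBin(anchorOne(loops), bs)
  j <- .anchorBin(anchorTwo(loops), bs)
  size <- 2 * w + 1
  acc <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  used <- 0
  for (k in seq_along(i)) {
    if (i[k] - w < 1 || j[k] + w > n || i[k] + w > n || j[k] - w < 1)
      next
    if (j[k] - i[k] <= 2 * w + 2) next
    W <- M[(i[k] - w):(i[k] + w), (j[k] - w):(j[k] + w)]
    ok <- is.finite(W)
    W[!ok] <- 0
    acc <- acc + W
    cnt <- cnt + ok
    used <- used + 1
  }
  if (used == 0) stop("zero valid loop windows")
  pile <- acc / cnt
  c0 <- w + 1
  centre <- mean(pile[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)],
                 na.rm = TRUE)
  corner <- function(ci, cj)
    pile[(ci - 1):(ci + 1), (cj - 1):(cj + 1)]
  bg <- mean(c(corner(2, 2), corner(2, size - 1),
               corner(size - 1, 2), corner(size - 1, size - 1)),
             na.rm = TRUE)
  list(apa = pile, centerRatio = centre / bg, n = used)
}

## anchor label set from state/peak overlap, resolved by precedence
.anchorLabel <- function(anchors, states, precedence) {
  st <- stateSegments(states)
  lab <- .stateLabelMap[as.character(mcols(st)$state)]
  keep <- !is.na(lab)
  st <- st[keep]
  lab <- lab[keep]
  hasC <- countOverlaps(anchors, ctcfPeaks(states)) > 0 &
    countOverlaps(anchors, cohesinPeaks(states)) > 0
  hits <- findOverlaps(anchors, st)
  labels <- lapply(seq_along(anchors), function(k) character(0))
  if (length(hits)) {
    byA <- split(lab[subjectHits(hits)], queryHits(hits))
    for (nm in names(byA))
      labels[[as.integer(nm)]] <- unique(byA[[nm]])
  }
  vapply(seq_along(anchors), function(k) {
    l <- labels[[k]]
    ## C requires both CTCF and cohesin peak support
    l <- setdiff(l, "C")
    if (hasC[k]) l <- c(l, "C")
    for (p in precedence) if (p %in% l) return(p)
    "none"
  }, "")
}

#' Classify loops by anchor chromatin state
#'
#' Labels each anchor against the state track and the CTCF/cohesin
#' peak sets (overlap = any intersection), resolves multi-label
#' anchors by the precedence P > E > B > C, and pairs the resolved
#' labels: (E, P) in either order gives EP, (P, P) gives PP, (B, B)
#' gives polycomb, and (C, C) -- which requires both a CTCF and a
#' cohesin peak at both anchors with no transcriptional label --
#' gives cohesin; everything else is "other". With empty annotation
#' inputs all loops are "other", with a warning.
#'
#' @param loops A \linkS4class{LoopSet}.
#' @param states A \linkS4class{ChromatinStateTrack}.
#' @param precedence Anchor label precedence (default P, E, B, C).
#' @return The \code{LoopSet} with \code{loopClass} set.
#' @export
classifyLoops <- function(loops, states,
                          precedence = c("P", "E", "B", "C")) {
  if (length(stateSegments(states)) == 0 &&
      length(ctcfPeaks(states)) == 0) {
    warning("empty annotation inputs; all loops classified 'other'")
    loopClass(loops) <- rep("other", length(loops))
    return(loops)
  }
  l1 <- .anchorLabel(anchorOne(loops), states, precedence)
  l2 <- .anchorLabel(anchorTwo(loops), states, precedence)
  cls <- vapply(seq_along(l1), function(k) {
    a <- sort(c(l1[k], l2[k]))
    if (all(a == c("E", "P"))) "EP"
    else if (all(a == c("P", "P"))) "PP"
    else if (all(a == c("B", "B"))) "polycomb"
    else if (all(a == c("C", "C"))) "cohesin"
    else "other"
  }, "")
  loopClass(loops) <- cls
  loops
}

#' Differential loop calls between two conditions
#'
#' Optionally median-centres each condition's scores (so a global
#' coverage shift does not masquerade as uniform change), then calls
#' each loop up/down/unchanged by the log2 fold-change against
#' \code{log2(fcThreshold)}. Loops with an undefined score in either
#' condition are excluded.
#'
#' @param scoresUT,scoresIAA Matched numeric score vectors (same loops,
#'   untreated and depleted).
#' @param fcThreshold Fold-change threshold (default 1.5).
#' @param medianCenter Median-centre per condition (default TRUE).
#' @return List: \code{calls} (data.frame: loop, log2fc, call),
#'   \code{fractions} (named up/down/unchanged, summing to 1),
#'   \code{meanUnchangedChange} (mean fractional intensity change of
#'   the unchanged set, on the uncentred scale).
#' @export
differentialLoops <- function(scoresUT, scoresIAA, fcThreshold = 1.5,
                              medianCenter = TRUE) {
  if (length(scoresUT) != length(scoresIAA))
    stop("score vectors must be matched")
  ok <- is.finite(scoresUT) & is.finite(scoresIAA)
  if (!any(ok)) stop("no loops scored in both conditions")
  ut <- scoresUT[ok]
  iaa <- scoresIAA[ok]
  utc <- ut
  iac <- iaa
  if (medianCenter) {
    utc <- ut / median(ut)
    iac <- iaa / median(iaa)
  }
  lfc <- log2(iac / utc)
  thr <- log2(fcThreshold)
  call <- ifelse(lfc > thr, "up", ifelse(lfc < -thr, "down",
                                         "unchanged"))
  fr <- c(up = mean(call == "up"), down = mean(call == "down"),
          unchanged = mean(call == "unchanged"))
  unchg <- call == "unchanged"
  meanChange <- if (any(unchg))
    mean(iaa[unchg] / ut[unchg] - 1) else NA_real_
  list(calls = data.frame(loop = which(ok), log2fc = lfc,
                          call = call),
       fractions = fr, meanUnchangedChange = meanChange)
}

#' Annotate loops by TAD-boundary crossing
#'
#' A loop is inter-TAD if at least one boundary lies strictly between
#' its anchor midpoints, excluding boundaries within \code{anchorZone}
#' of either midpoint (those set the anchor-at-boundary flag instead).
#' With no boundaries every loop is intra-TAD.
#'
#' @param loops A \linkS4class{LoopSet}.
#' @param boundaries Boundary positions in bp (numeric) or a
#'   \code{GRanges} of boundary bins (midpoints used).
#' @param anchorZone Exclusion half-width around anchor midpoints (bp,
#'   default 1000).
#' @return data.frame: crossing ("intra"/"inter"), nCrossed,
#'   anchorAtBoundary.
#' @export
annotateBoundaryCrossing <- function(loops, boundaries,
                                     anchorZone = 1000) {
  if (inherits(boundaries, "GRanges"))
    boundaries <- (start(boundaries) - 1 + end(boundaries)) / 2
  boundaries <- sort(boundaries)
  m1 <- (start(anchorOne(loops)) - 1 + end(anchorOne(loops))) / 2
  m2 <- (start(anchorTwo(loops)) - 1 + end(anchorTwo(loops))) / 2
  res <- t(vapply(seq_along(m1), function(k) {
    between <- boundaries > m1[k] & boundaries < m2[k]
    nearAnchor <- abs(boundaries - m1[k]) <= anchorZone |
      abs(boundaries - m2[k]) <= anchorZone
    c(nCrossed = sum(between & !nearAnchor),
      atBoundary = as.integer(any(nearAnchor)))
  }, c(nCrossed = 0, atBoundary = 0)))
  data.frame(crossing = ifelse(res[, 1] > 0, "inter", "intra"),
             nCrossed = res[, 1],
             anchorAtBoundary = res[, 2] > 0)
}

#' Fraction of inter-TAD loops retaining comparable intensity
#'
#' For each inter-TAD loop, builds the distance-matched intra-TAD
#' reference set (distance within +/- \code{band}) and counts the loop
#' comparable when its score is at least the reference median times
#' (1 - tolerance). Loops without any distance-matched reference are
#' excluded but counted.
#'
#' @param scoresInter,distInter Scores and distances (bp) of inter-TAD
#'   loops.
#' @param scoresIntra,distIntra Scores and distances of intra-TAD
#'   loops.
#' @param tolerance Tolerance band on the reference median (default 0).
#' @param band Distance-matching band (default 0.1 = +/-10 percent).
#' @return List: \code{fraction}, \code{nEvaluated}, \code{nExcluded}.
#' @export
crossingRetention <- function(scoresInter, distInter, scoresIntra,
                              distIntra, tolerance = 0, band = 0.1) {
  ok <- is.finite(scoresInter) & is.finite(distInter)
  scoresInter <- scoresInter[ok]
  distInter <- distInter[ok]
  okI <- is.finite(scoresIntra) & is.finite(distIntra)
  scoresIntra <- scoresIntra[okI]
  distIntra <- distIntra[okI]
  if (!length(scoresInter) || !length(scoresIntra))
    stop("both loop sets must be non-empty with defined scores")
  comparable <- 0
  evaluated <- 0
  excluded <- 0
  for (k in seq_along(scoresInter)) {
    ref <- scoresIntra[abs(distIntra - distInter[k]) <=
                         band * distInter[k]]
    if (!length(ref)) {
      excluded <- excluded + 1
      next
    }
    evaluated <- evaluated + 1
    if (scoresInter[k] >= median(ref) * (1 - tolerance))
      comparable <- comparable + 1
  }
  list(fraction = if (evaluated) comparable / evaluated else NA_real_,
       nEvaluated = evaluated, nExcluded = excluded)
}

#' Insulation profiles at crossed versus not-crossed boundaries
#'
#' Splits boundaries by whether at least one loop (optionally of a
#' given class) crosses them, and returns the mean insulation profile
#' over +/- \code{flankBp} around each group, plus optional occupancy
#' means over a supplied per-bin peak signal.
#'
#' @param boundaries Boundary \code{GRanges} (bins) or positions (bp).
#' @param loops A \linkS4class{LoopSet}.
#' @param insulation Insulation \code{GRanges} from
#'   \code{\link{insulationScore}}.
#' @param classFilter Optional loop class to restrict crossing loops.
#' @param flankBp Profile half-width (bp, default 5e5).
#' @param anchorZone Anchor exclusion zone as in
#'   \code{\link{annotateBoundaryCrossing}}.
#' @param occupancy Optional numeric per-insulation-bin signal whose
#'   group means at the boundary bins are reported.
#' @return List: \code{profiles} (matrix, rows = relative offsets,
#'   columns = groups), \code{groupSizes}, \code{occupancyMeans}.
#'   Empty groups are omitted with a warning.
#' @export
boundaryCrossedProfile <- function(boundaries, loops, insulation,
                                   classFilter = NULL, flankBp = 5e5,
                                   anchorZone = 1000,
                                   occupancy = NULL) {
  if (inherits(boundaries, "GRanges"))
    bpos <- (start(boundaries) - 1 + end(boundaries)) / 2
  else bpos <- boundaries
  if (!is.null(classFilter))
    loops <- loops[loopClass(loops) %in% classFilter]
  m1 <- (start(anchorOne(loops)) - 1 + end(anchorOne(loops))) / 2
  m2 <- (start(anchorTwo(loops)) - 1 + end(anchorTwo(loops))) / 2
  crossed <- vapply(bpos, function(b) {
    any(b > m1 & b < m2 & abs(b - m1) > anchorZone &
          abs(b - m2) > anchorZone)
  }, TRUE)
  binSizeIns <- width(insulation)[1]
  wBins <- round(flankBp / binSizeIns)
  score <- mcols(insulation)$score
  bbin <- floor(bpos / binSizeIns) + 1
  profile <- function(idx) {
    rows <- vapply(-wBins:wBins, function(off) {
      at <- bbin[idx] + off
      at <- at[at >= 1 & at <= length(score)]
      mean(score[at], na.rm = TRUE)
    }, 1)
    rows
  }
  groups <- list(crossed = which(crossed),
                 notCrossed = which(!crossed))
  empty <- vapply(groups, length, 1L) == 0
  if (any(empty)) {
    warning("empty group omitted: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  profs <- vapply(groups, profile, numeric(2 * wBins + 1))
  rownames(profs) <- as.character(-wBins:wBins)
  occ <- NULL
  if (!is.null(occupancy))
    occ <- vapply(groups, function(idx)
      mean(occupancy[bbin[idx]], na.rm = TRUE), 1)
  list(profiles = profs, groupSizes = vapply(groups, length, 1L),
       occupancyMeans = occ)
}
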