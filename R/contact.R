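## Contact-matrix core: orientation parsing, binning, ICE balancing,
## distance normalization and contact-decay statistics.

#' @importFrom stats rpois rnorm runif rexp rgeom var sd median
#'   quantile cor lm coef predict loess optimize integrate pnorm
#'   ks.test ecdf residuals
#' @importFrom utils head tail read.table write.table
NULL

#' Parse ligation orientation of contact pairs
#'
#' Maps the strand combination of a position-sorted intra-chromosomal
#' pair to its ligation-orientation class: (+,-) IN-IN, (+,+) IN-OUT,
#' (-,-) OUT-IN, (-,+) OUT-OUT. IN-OUT and OUT-IN are theoretically
#' interchangeable and merge to UNI when \code{mergeUni = TRUE}.
#'
#' @param strand1,strand2 Strand of the upstream/downstream read
#'   ("+"/"-"), vectorized.
#' @param mergeUni Merge IN-OUT and OUT-IN into "UNI" (default TRUE).
#' @return Character vector of orientation classes.
#' @export
parsePairOrientation <- function(strand1, strand2, mergeUni = TRUE) {
  if (!all(c(strand1, strand2) %in% c("+", "-")))
    stop("strands must be '+' or '-'")
  key <- paste0(strand1, strand2)
  cls <- c("+-" = "IN-IN", "++" = "IN-OUT", "--" = "OUT-IN",
           "-+" = "OUT-OUT")[key]
  if (mergeUni) cls[cls %in% c("IN-OUT", "OUT-IN")] <- "UNI"
  unname(cls)
}

#' Filter and orient contact pairs
#'
#' Position-sorts intra-chromosomal pairs, attaches the orientation
#' class and flags pairs with separation below \code{minSep} (self
#' ligation / undigested products) as removed.
#'
#' @param pairs data.frame with columns pos1, pos2, strand1, strand2
#'   (single chromosome).
#' @param minSep Minimum separation in bp (default 100).
#' @param mergeUni Merge IN-OUT/OUT-IN to UNI (default TRUE).
#' @return The input with added columns \code{orientation} and
#'   \code{removed}, positions sorted so pos1 <= pos2.
#' @export
orientPairs <- function(pairs, minSep = 100, mergeUni = TRUE) {
  swap <- pairs$pos1 > pairs$pos2
  if (any(swap)) {
    tmp <- pairs$pos1[swap]
    pairs$pos1[swap] <- pairs$pos2[swap]
    pairs$pos2[swap] <- tmp
    tmp <- pairs$strand1[swap]
    pairs$strand1[swap] <- pairs$strand2[swap]
    pairs$strand2[swap] <- tmp
  }
  pairs$orientation <- parsePairOrientation(pairs$strand1,
                                            pairs$strand2, mergeUni)
  pairs$removed <- (pairs$pos2 - pairs$pos1) < minSep
  pairs
}

#' Bin contact pairs into a matrix
#'
#' Assigns each pair to the (floor(pos1/binSize), floor(pos2/binSize))
#' cell (0-based half-open bins) and its transpose mirror. The pair
#' count is conserved exactly: the upper triangle plus diagonal sums to
#' the number of pairs.
#'
#' @param pairs data.frame with pos1, pos2 (bp, single chromosome).
#' @param binSize Bin width (bp, > 0).
#' @param chromLength Chromosome length (bp); positions beyond it are
#'   rejected.
#' @param chrom Chromosome name.
#' @return A \linkS4class{BinnedContactMatrix} of raw counts.
#' @export
binPairs <- function(pairs, binSize, chromLength, chrom = "chrS") {
  stopifnot(binSize > 0)
  if (any(pairs$pos1 < 0 | pairs$pos2 < 0 |
          pairs$pos1 >= chromLength | pairs$pos2 >= chromLength))
    stop("positions beyond chromosome length")
  n <- ceiling(chromLength / binSize)
  b1 <- floor(pairs$pos1 / binSize) + 1L
  b2 <- floor(pairs$pos2 / binSize) + 1L
  lo <- pmin(b1, b2)
  hi <- pmax(b1, b2)
  counts <- matrix(0, n, n)
  tab <- table(factor(lo, levels = seq_len(n)),
               factor(hi, levels = seq_len(n)))
  counts <- matrix(as.numeric(tab), n, n)
  counts[lower.tri(counts)] <- 0
  counts <- counts + t(counts * upper.tri(counts))
  BinnedContactMatrix(counts, chrom = chrom, binSize = binSize)
}

#' Iterative-correction (ICE) balancing
#'
#' Computes per-bin weights such that the balanced matrix
#' W C W has uniform unmasked row sums (relative variance below
#' \code{tol}), with the scale fixed so the mean corrected row sum is
#' 1. Low-coverage bins (coverage below \code{coverageFraction} of the
#' median) and all-zero bins are masked before iteration.
#'
#' @param x A raw \linkS4class{BinnedContactMatrix}.
#' @param tol Convergence tolerance on the relative variance of row
#'   sums (default 1e-5).
#' @param maxIter Maximum iterations (default 200).
#' @param maskLowCoverage Mask bins with coverage < coverageFraction *
#'   median coverage (default TRUE).
#' @param coverageFraction Masking threshold (default 0.1).
#' @return The matrix with \code{weights} filled in (NA on masked
#'   bins); counts unchanged. Errors with iteration diagnostics on
#'   non-convergence.
#' @export
balanceICE <- function(x, tol = 1e-5, maxIter = 200L,
                       maskLowCoverage = TRUE,
                       coverageFraction = 0.1) {
  C <- x@counts
  n <- nrow(C)
  if (n < 2) stop("need at least 2 bins")
  mask <- x@mask
  cov <- rowSums(C)
  mask <- mask | cov == 0
  if (maskLowCoverage) {
    med <- median(cov[!mask])
    mask <- mask | cov < coverageFraction * med
  }
  keep <- !mask
  if (sum(keep) < 2) stop("fewer than 2 unmasked bins")
  b <- rep(1, n)
  Ck <- C[keep, keep, drop = FALSE]
  bk <- b[keep]
  relvar <- Inf
  for (it in seq_len(maxIter)) {
    s <- as.vector(Ck %*% (1 / bk)) / bk
    relvar <- var(s) / mean(s)^2
    if (is.finite(relvar) && relvar < tol) break
    b1 <- s / mean(s)
    bk <- bk * b1
  }
  if (!(is.finite(relvar) && relvar < tol))
    stop(sprintf(paste0("ICE did not converge: relative variance ",
                        "%.3g after %d iterations (tol %.3g)"),
                 relvar, maxIter, tol))
  w <- rep(NA_real_, n)
  w[keep] <- 1 / bk
  ## fix scale: mean unmasked corrected row sum = 1
  bal <- outer(w[keep], w[keep]) * Ck
  w[keep] <- w[keep] / sqrt(mean(rowSums(bal)))
  x@weights <- w
  x@mask <- mask
  x
}

#' Balanced contact matrix
#'
#' Applies the stored balancing weights: balanced[i, j] =
#' w_i w_j counts[i, j]; masked rows/columns are NA.
#'
#' @param x A balanced \linkS4class{BinnedContactMatrix} (weights set).
#' @return Numeric matrix.
#' @export
balancedCounts <- function(x) {
  if (all(is.na(x@weights))) stop("matrix has no balancing weights")
  outer(x@weights, x@weights) * x@counts
}

#' Observed-over-expected normalization
#'
#' Divides each cell of the balanced matrix by the mean balanced value
#' of its diagonal (unmasked cells only), so every diagonal of the
#' output has mean 1. Diagonals with zero/undefined mean propagate NA.
#'
#' @param x A balanced \linkS4class{BinnedContactMatrix}, or one
#'   already carrying "balanced" normalization.
#' @return A \linkS4class{BinnedContactMatrix} with
#'   normalization "oe"; masked bins NA.
#' @export
observedOverExpected <- function(x) {
  B <- if (x@normalization == "oe") x@counts else balancedCounts(x)
  n <- nrow(B)
  d <- abs(as.vector(row(B) - col(B)))
  v <- as.vector(B)
  ok <- is.finite(v)
  sums <- rowsum(ifelse(ok, v, 0), d)
  cnts <- rowsum(ok + 0, d)
  mu <- as.vector(sums / cnts)  # mean per |diagonal|, NA-excluded
  mu[!is.finite(mu) | mu == 0] <- NA
  oe <- matrix(v / mu[d + 1], n, n)
  out <- x
  out@counts <- oe
  out@normalization <- "oe"
  out
}

## log-spaced distance-bin edges, 100 bp to 100 Mb
.decayBinEdges <- function(lo = 100, hi = 1e8, perDecade = 8) {
  10^seq(log10(lo), log10(hi), by = 1 / perDecade)
}

#' Contact-decay curve P(s) and its slope
#'
#' Computes the contact probability density P(s) in log-spaced
#' distance bins (default 100 bp to 100 Mb): the pair count per bin
#' divided by the bin width in bp and by the total number of valid
#' pairs after the short-range filter (so that P(s) integrates to the
#' orientation class's share of valid pairs), and the windowed
#' derivative of log P(s) against log s (least-squares slope over a
#' sliding window of log bins).
#'
#' @param pairs data.frame as accepted by \code{\link{orientPairs}}, or
#'   the output of \code{orientPairs}.
#' @param orientation One of "uni", "all", "inin", "outout".
#' @param minSep Short-range filter (bp, default 100).
#' @param binEdges Distance-bin edges (default log-spaced, 8 per
#'   decade, 100 bp - 100 Mb).
#' @param slopeWindow Window width in log bins for the slope curve
#'   (default 5, central difference).
#' @return List with \code{curve} (data.frame: smin, smax, center,
#'   count, prob) and \code{slope} (data.frame: center, slope).
#' @export
contactDecay <- function(pairs, orientation = c("uni", "all", "inin",
                                                "outout"),
                         minSep = 100, binEdges = .decayBinEdges(),
                         slopeWindow = 5L) {
  orientation <- match.arg(orientation)
  if (is.null(pairs$orientation))
    pairs <- orientPairs(pairs, minSep = minSep)
  valid <- !pairs$removed
  if (!any(valid)) stop("no valid pairs after short-range filter")
  nValid <- sum(valid)
  keep <- switch(orientation,
    uni = valid & pairs$orientation == "UNI",
    inin = valid & pairs$orientation == "IN-IN",
    outout = valid & pairs$orientation == "OUT-OUT",
    all = valid)
  s <- pairs$pos2[keep] - pairs$pos1[keep]
  cnt <- as.vector(table(cut(s, breaks = binEdges, right = FALSE)))
  curve <- data.frame(smin = head(binEdges, -1),
                      smax = tail(binEdges, -1))
  curve$center <- sqrt(curve$smin * curve$smax)
  curve$count <- cnt
  curve$prob <- cnt / nValid / (curve$smax - curve$smin)
  ## slope of log10 P vs log10 s in a sliding window of log bins
  ok <- which(curve$count > 0)
  slope <- data.frame(center = numeric(0), slope = numeric(0))
  if (length(ok) >= slopeWindow) {
    lx <- log10(curve$center[ok])
    ly <- log10(curve$prob[ok])
    half <- slopeWindow %/% 2
    cen <- (half + 1):(length(ok) - half)
    slp <- vapply(cen, function(i) {
      idx <- (i - half):(i + half)
      coef(lm(ly[idx] ~ lx[idx]))[2]
    }, 1)
    slope <- data.frame(center = curve$center[ok][cen], slope = slp)
  }
  list(curve = curve, slope = slope, orientation = orientation,
       nValid = nValid)
}
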