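## Domain-level structure: insulation-score TAD boundaries, compartment
## eigenvectors with sign correction, saddle compartment strength and
## rescaled aggregate-domain pileups.

#' Insulation score
#'
#' For each bin i, the mean balanced signal in the w x w diamond
#' crossing the diagonal at i (rows i-w+1..i, columns i+1..i+w),
#' expressed as log2 relative to the genome-wide mean diamond signal.
#' Defined only where the full diamond fits inside the matrix.
#'
#' @param x A balanced \linkS4class{BinnedContactMatrix}.
#' @param windowBp Diamond window size in bp (multiple of the bin
#'   size; must fit in the matrix).
#' @return \code{GRanges} of bins with mcols \code{score} (NA where
#'   undefined) and metadata \code{window}.
#' @export
insulationScore <- function(x, windowBp) {
  if (windowBp %% x@binSize != 0)
    stop("windowBp must be a multiple of the bin size")
  w <- windowBp / x@binSize
  n <- length(x)
  if (2 * w >= n) stop("window larger than matrix")
  B <- if (x@normalization == "raw") balancedCounts(x) else x@counts
  diam <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i < w || i + w > n) next
    diam[i] <- mean(B[(i - w + 1):i, (i + 1):(i + w)], na.rm = TRUE)
  }
  diam[is.nan(diam)] <- NA
  mu <- mean(diam, na.rm = TRUE)
  score <- log2(diam / mu)
  gr <- bins(x)
  mcols(gr)$score <- score
  S4Vectors::metadata(gr)$window <- windowBp
  gr
}

## prominence of a local minimum in a numeric track (NA-tolerant):
## min over both sides of (highest value reached before a lower
## minimum or the track edge) minus the minimum value
.minProminence <- function(v, i) {
  n <- length(v)
  side <- function(idx) {
    best <- -Inf
    for (j in idx) {
      if (is.na(v[j])) next
      if (v[j] < v[i]) break
      if (v[j] > best) best <- v[j]
    }
    best
  }
  left <- side(rev(seq_len(i - 1)))
  right <- side(if (i < n) (i + 1):n else integer(0))
  min(left, right) - v[i]
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score with prominence
#' at least \code{minProminence}; plateau ties break to the leftmost
#' bin.
#'
#' @param track Insulation \code{GRanges} from
#'   \code{\link{insulationScore}}.
#' @param minProminence Minimum prominence (default 0.1, in log2
#'   units).
#' @return \code{GRanges} of boundary bins with mcols
#'   \code{prominence} (boundary strength), sorted and unique.
#' @export
callBoundaries <- function(track, minProminence = 0.1) {
  v <- mcols(track)$score
  if (all(is.na(v))) stop("all-undefined insulation track")
  n <- length(v)
  mins <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    ## previous and next non-NA neighbours
    l <- i - 1
    while (l >= 1 && is.na(v[l])) l <- l - 1
    r <- i + 1
    while (r <= n && is.na(v[r])) r <- r + 1
    lv <- if (l >= 1) v[l] else Inf
    rv <- if (r <= n) v[r] else Inf
    ## leftmost bin of a plateau counts as the minimum
    if (v[i] < lv && v[i] <= rv) mins <- c(mins, i)
  }
  if (length(mins)) {
    prom <- vapply(mins, function(i) .minProminence(v, i), 1)
    keep <- is.finite(prom) & prom >= minProminence
    mins <- mins[keep]
    prom <- prom[keep]
  } else prom <- numeric(0)
  out <- track[mins]
  mcols(out) <- NULL
  mcols(out)$prominence <- prom
  out
}

#' Compartment eigenvector with sign correction
#'
#' First eigenvector of the Pearson correlation matrix of the O/E map
#' (unmasked bins), sign-fixed so that its correlation with an active
#' chromatin signal is positive (positive values = A compartment).
#'
#' @param x An O/E \linkS4class{BinnedContactMatrix} (typically coarse
#'   bins, e.g. 200 kb).
#' @param activeSignal Numeric per-bin active-mark signal used to
#'   anchor the sign.
#' @return \code{GRanges} of bins with mcols \code{E1} (NA on masked
#'   bins).
#' @export
compartmentEigenvector <- function(x, activeSignal) {
  if (x@normalization != "oe")
    stop("compartmentEigenvector expects an O/E matrix")
  M <- x@counts
  keep <- which(colSums(is.finite(M)) > 0)
  if (length(keep) < 10) stop("need at least 10 unmasked bins")
  Mk <- M[keep, keep]
  if (all(is.finite(Mk)) && sd(as.vector(Mk)) == 0)
    stop("no compartment signal: constant matrix")
  P <- suppressWarnings(cor(Mk, use = "pairwise.complete.obs"))
  if (any(!is.finite(P)))
    stop("no compartment signal: degenerate correlation matrix")
  eig <- eigen(P, symmetric = TRUE)
  e1 <- eig$vectors[, 1] * sqrt(abs(eig$values[1]))
  a <- activeSignal[keep]
  if (sd(a) > 0 && sd(e1) > 0 && cor(e1, a) < 0) e1 <- -e1
  out <- rep(NA_real_, length(x))
  out[keep] <- e1
  gr <- bins(x)
  mcols(gr)$E1 <- out
  gr
}

#' Saddle plot and compartment strength
#'
#' Orders bins by increasing eigenvector value, groups them into
#' quantiles, and averages the O/E signal over every quantile pair
#' (off-diagonal cells, i != j). Compartment strength is
#' mean(AA and BB corners) / mean(AB and BA corners) over the extreme
#' \code{cornerFraction} of quantiles.
#'
#' @param x An O/E \linkS4class{BinnedContactMatrix}.
#' @param e1 Numeric per-bin eigenvector (or GRanges from
#'   \code{\link{compartmentEigenvector}}).
#' @param nQuantiles Number of quantile groups (default 5).
#' @param cornerFraction Fraction of quantiles per corner (default
#'   0.2).
#' @return List: \code{saddle} (nQuantiles x nQuantiles mean O/E,
#'   increasing E1), \code{strength}.
#' @export
saddlePlot <- function(x, e1, nQuantiles = 5, cornerFraction = 0.2) {
  if (inherits(e1, "GRanges")) e1 <- mcols(e1)$E1
  M <- x@counts
  keep <- which(is.finite(e1))
  if (nQuantiles > length(keep))
    stop("nQuantiles exceeds number of bins with defined E1")
  q <- cut(rank(e1[keep], ties.method = "first"),
           breaks = nQuantiles, labels = FALSE)
  S <- matrix(NA_real_, nQuantiles, nQuantiles)
  for (a in seq_len(nQuantiles)) for (b in seq_len(nQuantiles)) {
    ia <- keep[q == a]
    ib <- keep[q == b]
    block <- M[ia, ib, drop = FALSE]
    if (a == b) diag(block) <- NA
    S[a, b] <- mean(block, na.rm = TRUE)
  }
  nc <- max(1, round(cornerFraction * nQuantiles))
  lo <- seq_len(nc)
  hi <- seq(nQuantiles - nc + 1, nQuantiles)
  strength <- mean(c(S[lo, lo], S[hi, hi]), na.rm = TRUE) /
    mean(c(S[lo, hi], S[hi, lo]), na.rm = TRUE)
  list(saddle = S, strength = strength)
}

## map source bins onto out pixels by fractional (area-weighted) overlap
.rescaleOperator <- function(nIn, nOut) {
  M <- matrix(0, nOut, nIn)
  edges <- seq(0, nIn, length.out = nOut + 1)
  for (p in seq_len(nOut)) {
    lo <- edges[p]
    hi <- edges[p + 1]
    for (b in seq_len(nIn)) {
      ov <- min(hi, b) - max(lo, b - 1)
      if (ov > 0) M[p, b] <- ov
    }
    M[p, ] <- M[p, ] / (hi - lo)
  }
  M
}

#' Aggregate domain analysis (rescaled domain pileup)
#'
#' Each domain window (the domain plus half a domain length of flank on
#' each side) is rescaled to \code{outSize} x \code{outSize} pixels by
#' area-weighted interpolation and the windows averaged. Domains whose
#' window falls outside the matrix are skipped with a warning.
#'
#' @param x An O/E \linkS4class{BinnedContactMatrix}.
#' @param domains Two-column matrix/data.frame of domain intervals
#'   (bp), or a \code{GRanges}.
#' @param outSize Output pixels per side (default 30).
#' @return List: \code{pileup} (outSize x outSize), \code{n} domains
#'   used, \code{interiorFlankRatio} (mean over the central half of the
#'   pileup divided by mean outside it).
#' @export
aggregateDomains <- function(x, domains, outSize = 30L) {
  if (inherits(domains, "GRanges"))
    domains <- cbind(start(domains) - 1, end(domains))
  domains <- as.matrix(domains)
  if (nrow(domains) < 1) stop("need at least one domain")
  M <- x@counts
  n <- nrow(M)
  bs <- x@binSize
  acc <- matrix(0, outSize, outSize)
  wts <- matrix(0, outSize, outSize)
  used <- 0
  skipped <- 0
  for (k in seq_len(nrow(domains))) {
    d1 <- domains[k, 1]
    d2 <- domains[k, 2]
    len <- d2 - d1
    if (len < 3 * bs) {
      skipped <- skipped + 1
      next
    }
    lo <- floor((d1 - len / 2) / bs) + 1
    hi <- ceiling((d2 + len / 2) / bs)
    if (lo < 1 || hi > n) {
      skipped <- skipped + 1
      next
    }
    W <- M[lo:hi, lo:hi]
    R <- .rescaleOperator(nrow(W), outSize)
    ok <- is.finite(W)
    W0 <- W
    W0[!ok] <- 0
    num <- R %*% W0 %*% t(R)
    den <- R %*% (ok + 0) %*% t(R)
    acc <- acc + num
    wts <- wts + den
    used <- used + 1
  }
  if (used == 0) stop("no usable domains")
  if (skipped > 0)
    warning(skipped, " domain(s) skipped (outside matrix or < 3 bins)")
  pile <- acc / wts
  idx <- seq_len(outSize)
  interior <- idx > outSize / 4 & idx <= 3 * outSize / 4
  interiorMask <- outer(interior, interior, "&")
  ratio <- mean(pile[interiorMask], na.rm = TRUE) /
    mean(pile[!interiorMask], na.rm = TRUE)
  list(pileup = pile, n = used, interiorFlankRatio = ratio)
}
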