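## Expression linkage: anchor expression assignment, metagene
## profiles, LOESS strength-expression curves, DEG enrichment and
## differential-score CDF shifts.

#' @importFrom GenomicRanges coverage
NULL

#' Assign gene expression to loops
#'
#' Per loop, the mean TPM of genes whose TSS lies within +/-
#' \code{flank} of either anchor midpoint (union of the two anchors,
#' each gene counted once). Loops with no nearby gene get NA. With
#' \code{anchors = "promoter"} only genes at the second (promoter-side)
#' anchor are averaged.
#'
#' @param loops A \linkS4class{LoopSet}.
#' @param genes data.frame with columns \code{tss} and \code{tpm}.
#' @param flank Flank around anchor midpoints (bp, default 5000).
#' @param anchors "both" (default) or "promoter".
#' @return Numeric expression per loop.
#' @export
assignExpression <- function(loops, genes, flank = 5000,
                             anchors = c("both", "promoter")) {
  anchors <- match.arg(anchors)
  m1 <- (start(anchorOne(loops)) - 1 + end(anchorOne(loops))) / 2
  m2 <- (start(anchorTwo(loops)) - 1 + end(anchorTwo(loops))) / 2
  vapply(seq_along(m1), function(k) {
    near2 <- abs(genes$tss - m2[k]) <= flank
    hit <- if (anchors == "both")
      abs(genes$tss - m1[k]) <= flank | near2 else near2
    if (!any(hit)) NA_real_ else mean(genes$tpm[hit])
  }, 1)
}

## per-bp signal vector over [from, to) from a score-weighted coverage
.signalWindow <- function(cov, from, to) {
  n <- length(cov)
  lo <- max(1, from)
  hi <- min(n, to)
  out <- rep(0, to - from + 1)
  if (hi >= lo)
    out[(lo - from + 1):(hi - from + 1)] <-
      as.numeric(cov[lo:hi])
  out
}

#' Metagene profile over rescaled gene bodies
#'
#' Gene bodies (TSS to TES, strand-aware: minus-strand genes are
#' reversed) are rescaled to \code{nBodyBins} bins by area-weighted
#' averaging; flanks of \code{flankBp} are kept at \code{flankBins}
#' native-resolution bins. Genes shorter than one body bin are skipped
#' and counted.
#'
#' @param genes data.frame with tss, tes, strand columns.
#' @param signal \code{GRanges} with a numeric \code{score} column
#'   (bedGraph-like), single chromosome.
#' @param groups Optional factor per gene; one profile per level.
#' @param nBodyBins Body bins (default 50).
#' @param flankBp Flank width (bp, default 2000).
#' @param flankBins Bins per flank (default 20).
#' @return List: \code{profiles} (matrix, rows = positions
#'   upstream-flank/body/downstream-flank, columns = groups),
#'   \code{nSkipped}.
#' @export
metageneProfile <- function(genes, signal, groups = NULL,
                            nBodyBins = 50L, flankBp = 2000,
                            flankBins = 20L) {
  cov <- coverage(signal, weight = mcols(signal)$score)[[1]]
  if (is.null(groups)) groups <- factor(rep("all", nrow(genes)))
  groups <- as.factor(groups)
  nTot <- flankBins + nBodyBins + flankBins
  prof <- matrix(0, nTot, nlevels(groups),
                 dimnames = list(NULL, levels(groups)))
  cnt <- integer(nlevels(groups))
  skipped <- 0
  R <- NULL
  for (g in seq_len(nrow(genes))) {
    tss <- genes$tss[g]
    tes <- genes$tes[g]
    minus <- genes$strand[g] == "-"
    bodyLen <- abs(tes - tss)
    if (bodyLen < nBodyBins) {
      skipped <- skipped + 1
      next
    }
    lo <- min(tss, tes)
    hi <- max(tss, tes)
    body <- .signalWindow(cov, lo + 1, hi)
    Rb <- .rescaleOperator(length(body), nBodyBins)
    bodyBins <- as.vector(Rb %*% body)
    up <- .signalWindow(cov, lo - flankBp + 1, lo)
    dn <- .signalWindow(cov, hi + 1, hi + flankBp)
    Rf <- .rescaleOperator(flankBp, flankBins)
    upBins <- as.vector(Rf %*% up)
    dnBins <- as.vector(Rf %*% dn)
    v <- c(upBins, bodyBins, dnBins)
    if (minus) v <- rev(v)
    gi <- as.integer(groups[g])
    prof[, gi] <- prof[, gi] + v
    cnt[gi] <- cnt[gi] + 1L
  }
  for (gi in seq_along(cnt))
    if (cnt[gi] > 0) prof[, gi] <- prof[, gi] / cnt[gi]
  list(profiles = prof, nGenes = cnt, nSkipped = skipped)
}

#' LOESS loop-strength versus expression curve
#'
#' Ranks loops by log1p(TPM) and fits a local-linear LOESS (tricube
#' weights) of loop score against the rank, returning the fitted curve
#' with its standard-error band.
#'
#' @param scores Loop scores.
#' @param expression Expression (TPM) per loop; NA pairs dropped.
#' @param span LOESS span (default 0.5).
#' @return data.frame: rank, fit, se (ordered by rank). Errors with
#'   fewer than 20 complete pairs.
#' @export
strengthExpressionCurve <- function(scores, expression, span = 0.5) {
  ok <- is.finite(scores) & is.finite(expression)
  if (sum(ok) < 20) stop("need at least 20 loops with score and ",
                         "expression")
  x <- rank(log1p(expression[ok]), ties.method = "first")
  y <- scores[ok]
  fit <- loess(y ~ x, span = span, degree = 1,
               family = "gaussian")
  o <- order(x)
  pr <- predict(fit, newdata = data.frame(x = x[o]), se = TRUE)
  data.frame(rank = x[o], fit = pr$fit, se = pr$se.fit)
}

#' DEG enrichment at loop anchors or TAD boundaries
#'
#' log2 of the ratio between the fraction of differential genes with a
#' TSS within +/- \code{flank} of a feature and the same fraction for
#' unaffected genes, with a gene-label permutation p-value.
#'
#' @param genes data.frame with tss and deg_status ("up"/"down"/"no").
#' @param features Feature positions (bp) or \code{GRanges}
#'   (midpoints used): loop anchors or boundaries.
#' @param flank Flank (bp, default 5000).
#' @param nPerm Permutation draws (default 1000).
#' @param seed Seed for the permutation null.
#' @return List: \code{enrichment} (log2; NA if the background
#'   fraction is zero), \code{p}, \code{fracDEG}, \code{fracBackground}.
#' @export
degAnchorEnrichment <- function(genes, features, flank = 5000,
                                nPerm = 1000L, seed = 1L) {
  if (inherits(features, "GRanges"))
    features <- (start(features) - 1 + end(features)) / 2
  isDeg <- genes$deg_status != "no"
  if (!any(isDeg) || all(isDeg))
    stop("need non-empty DEG and background gene sets")
  nearFeature <- vapply(genes$tss, function(t)
    any(abs(features - t) <= flank), TRUE)
  frac <- function(lab) mean(nearFeature[lab])
  fD <- frac(isDeg)
  fB <- frac(!isDeg)
  if (fB == 0)
    return(list(enrichment = NA_real_, p = NA_real_, fracDEG = fD,
                fracBackground = fB))
  enr <- log2(fD / fB)
  set.seed(seed)
  permEnr <- vapply(seq_len(nPerm), function(b) {
    lab <- sample(isDeg)
    fDb <- frac(lab)
    fBb <- frac(!lab)
    if (fDb == 0 || fBb == 0) return(NA_real_)
    log2(fDb / fBb)
  }, 1)
  p <- (1 + sum(abs(permEnr) >= abs(enr), na.rm = TRUE)) /
    (1 + sum(is.finite(permEnr)))
  list(enrichment = enr, p = p, fracDEG = fD, fracBackground = fB)
}

#' CDF of differential loop scores at DEG promoters
#'
#' Splits loops into those anchored within \code{promoterWindow} of a
#' differential-gene promoter versus an unaffected-gene promoter and
#' compares the two differential-score distributions
#' (Kolmogorov-Smirnov). A negative shift means the DEG group lost
#' more contact intensity.
#'
#' @param diffScores Differential score per loop (depleted minus
#'   untreated).
#' @param loops A \linkS4class{LoopSet}.
#' @param genes data.frame with tss and deg_status.
#' @param promoterWindow Anchor-promoter window (bp, default 1000).
#' @return List: \code{deg}, \code{background} (scores per group),
#'   \code{ks} (htest or NULL), \code{shift} (median difference,
#'   DEG minus background). Warns when a group has fewer than 10
#'   loops; with an empty DEG group returns the single background
#'   curve.
#' @export
degLoopCdf <- function(diffScores, loops, genes,
                       promoterWindow = 1000) {
  m1 <- (start(anchorOne(loops)) - 1 + end(anchorOne(loops))) / 2
  m2 <- (start(anchorTwo(loops)) - 1 + end(anchorTwo(loops))) / 2
  degT <- genes$tss[genes$deg_status != "no"]
  noT <- genes$tss[genes$deg_status == "no"]
  nearAny <- function(m, tss) {
    if (!length(tss)) return(rep(FALSE, length(m)))
    vapply(m, function(x) any(abs(tss - x) <= promoterWindow), TRUE)
  }
  atDeg <- nearAny(m1, degT) | nearAny(m2, degT)
  atNo <- (nearAny(m1, noT) | nearAny(m2, noT)) & !atDeg
  gD <- diffScores[atDeg & is.finite(diffScores)]
  gB <- diffScores[atNo & is.finite(diffScores)]
  if (!length(gD)) {
    warning("empty DEG group; returning single background curve")
    return(list(deg = numeric(0), background = gB, ks = NULL,
                shift = NA_real_))
  }
  if (length(gD) < 10 || length(gB) < 10)
    warning("group with fewer than 10 loops")
  ks <- suppressWarnings(ks.test(gD, gB))
  list(deg = gD, background = gB, ks = ks,
       shift = median(gD) - median(gB))
}
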