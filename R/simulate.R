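## Synthetic-data generators: every input the pipeline consumes, with
## known ground truth, at desk scale.

#' Configuration for the synthetic contact-map generator
#'
#' Defines the generative model for a single-chromosome contact map:
#' power-law distance decay, TAD blocks with boundary insulation, and
#' planted focal dots (loops) as isotropic Gaussian bumps in bin space.
#' The expected count at bins (i, j) is
#' N * s^(-alpha) * beta^[same TAD] * gamma^(boundaries crossed) *
#' prod(1 + (a - 1) * exp(-d^2 / (2 sigma_dot^2))) over planted dots,
#' scaled so the total expectation equals \code{depth}; counts are
#' Poisson.
#'
#' @param chromLength Chromosome length (bp).
#' @param binSize Bin width (bp); must divide chromLength.
#' @param decayExponent Power-law decay exponent alpha (> 0).
#' @param tadIntervals Two-column matrix/data.frame of non-overlapping
#'   sorted TAD intervals (bp, 0-based half-open), or NULL.
#' @param intraTadFactor Within-TAD enrichment beta (>= 1).
#' @param boundaryInsulation Per-boundary multiplier gamma in (0, 1].
#' @param dots data.frame with columns anchor1, anchor2 (bp), amplitude
#'   (>= 1), sigma (bins) and class (cohesin/EP/PP/polycomb), or NULL.
#' @param depth Expected total count (upper triangle plus diagonal).
#' @param chrom Chromosome name.
#' @return A \code{simConfig} list, validated.
#' @export
simConfig <- function(chromLength, binSize, decayExponent = 1,
                      tadIntervals = NULL, intraTadFactor = 1,
                      boundaryInsulation = 1, dots = NULL,
                      depth = 1e6, chrom = "chrS") {
  if (chromLength %% binSize != 0)
    stop("binSize must divide chromLength")
  if (decayExponent <= 0) stop("decayExponent must be > 0")
  if (intraTadFactor < 1) stop("intraTadFactor must be >= 1")
  if (boundaryInsulation <= 0 || boundaryInsulation > 1)
    stop("boundaryInsulation must be in (0, 1]")
  if (!is.null(tadIntervals)) {
    tadIntervals <- as.matrix(tadIntervals)
    if (ncol(tadIntervals) != 2) stop("tadIntervals needs two columns")
    o <- order(tadIntervals[, 1])
    tadIntervals <- tadIntervals[o, , drop = FALSE]
    if (any(tadIntervals[, 2] <= tadIntervals[, 1]))
      stop("tadIntervals must have start < end")
    if (nrow(tadIntervals) > 1 &&
        any(tadIntervals[-1, 1] < tadIntervals[-nrow(tadIntervals), 2]))
      stop("tadIntervals must be non-overlapping")
    if (any(tadIntervals < 0) || any(tadIntervals > chromLength))
      stop("tadIntervals outside chromosome")
  }
  if (!is.null(dots)) {
    dots <- as.data.frame(dots)
    need <- c("anchor1", "anchor2", "amplitude")
    if (!all(need %in% colnames(dots)))
      stop("dots needs columns anchor1, anchor2, amplitude")
    if (is.null(dots$sigma)) dots$sigma <- 1.5
    if (is.null(dots$class)) dots$class <- "other"
    if (any(dots$anchor1 < 0) || any(dots$anchor2 > chromLength) ||
        any(dots$anchor1 > chromLength))
      stop("dot anchors outside chromosome")
    if (any(dots$amplitude < 1)) stop("dot amplitude must be >= 1")
    swap <- dots$anchor1 > dots$anchor2
    if (any(swap)) {
      tmp <- dots$anchor1[swap]
      dots$anchor1[swap] <- dots$anchor2[swap]
      dots$anchor2[swap] <- tmp
    }
  }
  structure(list(chromLength = chromLength, binSize = binSize,
                 decayExponent = decayExponent,
                 tadIntervals = tadIntervals,
                 intraTadFactor = intraTadFactor,
                 boundaryInsulation = boundaryInsulation, dots = dots,
                 depth = depth, chrom = chrom), class = "simConfig")
}

## TAD membership (0 = no TAD) per bin, using bin midpoints
.tadIndex <- function(config) {
  n <- config$chromLength / config$binSize
  mid <- (seq_len(n) - 0.5) * config$binSize
  idx <- integer(n)
  ti <- config$tadIntervals
  if (!is.null(ti))
    for (k in seq_len(nrow(ti)))
      idx[mid >= ti[k, 1] & mid < ti[k, 2]] <- k
  idx
}

## internal boundary positions (bp) implied by the TAD intervals
.tadBoundaries <- function(config) {
  ti <- config$tadIntervals
  if (is.null(ti)) return(numeric(0))
  b <- sort(unique(as.vector(ti)))
  b[b > 0 & b < config$chromLength]
}

#' Simulate a binned contact map with planted structure
#'
#' Draws a Poisson contact map from the generative model described in
#' \code{\link{simConfig}} and returns it together with the ground
#' truth (planted loops, boundary positions, expected matrix).
#'
#' @param config A \code{\link{simConfig}}.
#' @param seed Integer seed (determinism contract: same seed, same map).
#' @return List with elements \code{map}
#'   (\linkS4class{BinnedContactMatrix}), \code{truth} (list: loops as a
#'   \linkS4class{LoopSet} with mcols-free amplitude vector in
#'   \code{truth$amplitude}, boundaries in bp, tadIntervals, config) and
#'   \code{expected} (noiseless expected matrix).
#' @export
simulateContactMap <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simConfig"))
  bs <- config$binSize
  n <- config$chromLength / bs
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  s[s == 0] <- 1  # diagonal treated as separation of one bin
  E <- s^(-config$decayExponent)
  tad <- .tadIndex(config)
  if (config$intraTadFactor > 1) {
    same <- outer(tad, tad, "==") & tad > 0
    E[same] <- E[same] * config$intraTadFactor
  }
  bnd <- .tadBoundaries(config)
  if (length(bnd) && config$boundaryInsulation < 1) {
    crossed <- Reduce("+", lapply(seq_along(bnd), function(k) {
      lo <- (seq_len(n) - 0.5) * bs < bnd[k]
      outer(lo, !lo, "&") | outer(!lo, lo, "&")
    }))
    E <- E * config$boundaryInsulation^crossed
  }
  dots <- config$dots
  if (!is.null(dots) && nrow(dots)) {
    for (k in seq_len(nrow(dots))) {
      i0 <- floor(dots$anchor1[k] / bs) + 1
      j0 <- floor(dots$anchor2[k] / bs) + 1
      a <- dots$amplitude[k]
      sg <- dots$sigma[k]
      wrad <- ceiling(4 * sg)
      ii <- max(1, i0 - wrad):min(n, i0 + wrad)
      jj <- max(1, j0 - wrad):min(n, j0 + wrad)
      d2 <- outer((ii - i0)^2, (jj - j0)^2, "+")
      bump <- 1 + (a - 1) * exp(-d2 / (2 * sg^2))
      E[ii, jj] <- E[ii, jj] * bump
      E[jj, ii] <- E[jj, ii] * t(bump)  # mirror below the diagonal
    }
  }
  E <- E * config$depth / sum(E[upper.tri(E, diag = TRUE)])
  set.seed(seed)
  counts <- matrix(0, n, n)
  ut <- upper.tri(counts, diag = TRUE)
  counts[ut] <- rpois(sum(ut), E[ut])
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  map <- BinnedContactMatrix(counts, chrom = config$chrom, binSize = bs)
  truth <- list(boundaries = bnd, tadIntervals = config$tadIntervals,
                config = config)
  if (!is.null(dots) && nrow(dots)) {
    a1 <- GRanges(config$chrom,
                  IRanges(start = floor(dots$anchor1 / bs) * bs + 1,
                          width = bs))
    a2 <- GRanges(config$chrom,
                  IRanges(start = floor(dots$anchor2 / bs) * bs + 1,
                          width = bs))
    truth$loops <- LoopSet(a1, a2, loopClass = as.character(dots$class))
    truth$amplitude <- dots$amplitude
  } else {
    truth$loops <- LoopSet(GRanges(), GRanges())
    truth$amplitude <- numeric(0)
  }
  list(map = map, truth = truth, expected = E)
}

#' Simulate a chromatin-state annotation track from planted truth
#'
#' Propagates the planted loop classes into a 12-state annotation:
#' cohesin anchors receive CTCF and cohesin peaks plus a CTCF/insulator
#' segment; EP dots one enhancer and one active-promoter segment (the
#' downstream anchor is the promoter); PP dots two promoter segments;
#' polycomb dots two polycomb-repressor segments. Background is
#' intergenic. Anchors shared by conflicting classes carry all labels
#' (multi-label contract), with a warning.
#'
#' @param truth Ground-truth list from \code{\link{simulateContactMap}}.
#' @return A \linkS4class{ChromatinStateTrack}.
#' @export
simulateAnnotations <- function(truth) {
  loops <- truth$loops
  config <- truth$config
  chrom <- config$chrom
  segs <- GRanges(chrom, IRanges(1, config$chromLength))
  mcols(segs)$state <- "intergenic"
  ctcf <- GRanges()
  coh <- GRanges()
  if (length(loops)) {
    cls <- loopClass(loops)
    addSeg <- function(gr, state) {
      mcols(gr) <- NULL
      mcols(gr)$state <- state
      gr
    }
    out <- list(segs)
    for (k in seq_along(loops)) {
      a1 <- anchorOne(loops)[k]
      a2 <- anchorTwo(loops)[k]
      if (cls[k] == "cohesin") {
        out <- c(out, list(addSeg(a1, "CTCF/insulator"),
                           addSeg(a2, "CTCF/insulator")))
        ctcf <- c(ctcf, granges(a1), granges(a2))
        coh <- c(coh, granges(a1), granges(a2))
      } else if (cls[k] == "EP") {
        out <- c(out, list(addSeg(a1, "strong enhancer"),
                           addSeg(a2, "active promoter")))
      } else if (cls[k] == "PP") {
        out <- c(out, list(addSeg(a1, "active promoter"),
                           addSeg(a2, "active promoter")))
      } else if (cls[k] == "polycomb") {
        out <- c(out, list(addSeg(a1, "polycomb repressor"),
                           addSeg(a2, "polycomb repressor")))
      }
    }
    segs <- do.call(c, out)
    ## warn when one anchor interval carries conflicting class labels
    anno <- segs[mcols(segs)$state != "intergenic"]
    if (length(anno) > 1) {
      hits <- findOverlaps(anno, anno)
      hits <- hits[queryHits(hits) < subjectHits(hits)]
      confl <- mcols(anno)$state[queryHits(hits)] !=
        mcols(anno)$state[subjectHits(hits)]
      if (any(confl))
        warning("overlapping anchors with conflicting labels; ",
                "both labels emitted")
    }
  }
  ChromatinStateTrack(segs, ctcfPeaks = ctcf, cohesinPeaks = coh)
}

#' Kinetic simulation parameters
#'
#' Parameters for the single-molecule simulators: three-state occupancy
#' (bound/slow/fast), apparent diffusion coefficients, localization
#' error, acquisition timing, photobleaching and axial detection depth,
#' and dissociation-rate mixture for binding-duration/FRAP simulation.
#' Defaults reproduce a YY1-like nuclear factor imaged by stroboscopic
#' SPT at ~133 Hz: ~31 percent bound, ~26 percent slow, ~43 percent
#' fast, with D = 0.005, 0.5, 5 um^2/s and 35-nm localization error.
#'
#' @param fractions Named or ordered numeric (bound, slow, fast);
#'   nonnegative, sum 1 within 1e-9.
#' @param D Diffusion coefficients (um^2/s), strictly increasing.
#' @param sigmaLoc Localization error (um).
#' @param frameInterval Frame interval (s).
#' @param exposure Exposure time (s).
#' @param kBleach Photobleach probability per frame.
#' @param halfDepth Axial detection half-depth (um).
#' @param kOff Dissociation-rate component(s) (1/s).
#' @param kOffWeights Mixture weights for \code{kOff} (sum 1).
#' @return A \code{kineticParams} list, validated.
#' @export
kineticParams <- function(fractions = c(bound = 0.31, slow = 0.26,
                                        fast = 0.43),
                          D = c(0.005, 0.5, 5), sigmaLoc = 0.035,
                          frameInterval = 0.0075,
                          exposure = 0.001, kBleach = 0.1,
                          halfDepth = 0.7, kOff = 1 / 13,
                          kOffWeights = 1) {
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (length(D) != length(fractions))
    stop("D and fractions must have equal length")
  if (is.unsorted(D, strictly = TRUE))
    stop("D must be strictly increasing (bound < slow < fast)")
  if (abs(sum(kOffWeights) - 1) > 1e-9)
    stop("kOffWeights must sum to 1")
  if (length(kOff) != length(kOffWeights))
    stop("kOff and kOffWeights must have equal length")
  structure(list(fractions = fractions, D = D, sigmaLoc = sigmaLoc,
                 frameInterval = frameInterval, exposure = exposure,
                 kBleach = kBleach, halfDepth = halfDepth, kOff = kOff,
                 kOffWeights = kOffWeights), class = "kineticParams")
}

#' Simulate single-particle trajectories
#'
#' Each molecule is assigned a diffusion state by the occupancy weights
#' (no within-trajectory switching by default); xy positions evolve by
#' 2D Brownian steps (variance 2 D dt per axis) observed with Gaussian
#' localization error. Trajectories are truncated by photobleaching
#' (geometric, per frame) and by axial defocalization: an absorbing
#' boundary at +/- halfDepth on a z random walk with the same D,
#' starting uniform in the detection slab. Molecules lost before their
#' second frame appear as single-localization trajectories.
#'
#' @param params A \code{\link{kineticParams}}.
#' @param n Number of molecules (> 0).
#' @param seed Integer seed.
#' @param stateSwitching If TRUE, molecules re-draw their state each
#'   frame (stress-test option; default FALSE).
#' @param maxFrames Hard cap on trajectory length.
#' @return A \linkS4class{TrajectorySet}; the true state per trajectory
#'   is stored in \code{attr(, "trueState")}.
#' @export
simulateTrajectories <- function(params, n, seed = 1L,
                                 stateSwitching = FALSE,
                                 maxFrames = 200L) {
  stopifnot(inherits(params, "kineticParams"))
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  nstate <- length(params$fractions)
  state <- sample.int(nstate, n, replace = TRUE,
                      prob = params$fractions)
  dt <- params$frameInterval
  h <- params$halfDepth
  ## frames survived before bleaching (at least the first frame)
  nb <- if (params$kBleach > 0)
    pmin(rgeom(n, params$kBleach) + 1L, maxFrames) else
    rep(maxFrames, n)
  nf <- nb
  if (stateSwitching) {
    ## per-frame state redraws: axial exit molecule-by-molecule
    for (m in seq_len(n)) {
      stvec <- sample.int(nstate, nb[m], replace = TRUE,
                          prob = params$fractions)
      if (is.finite(h) && nb[m] > 1) {
        sdstep <- sqrt(2 * params$D[stvec] * dt)
        z <- runif(1, -h, h) +
          cumsum(c(0, rnorm(nb[m] - 1, 0, sdstep[-nb[m]])))
        exit <- which(abs(z) > h)
        if (length(exit)) nf[m] <- max(1L, exit[1] - 1L)
      }
    }
  }
  if (!stateSwitching && is.finite(h)) {
    ## axial first-exit, vectorized within each state
    for (st in seq_len(nstate)) {
      idx <- which(state == st)
      if (!length(idx)) next
      nmax <- max(nb[idx])
      sdz <- sqrt(2 * params$D[st] * dt)
      if (sdz == 0) next
      steps <- matrix(rnorm((nmax - 1) * length(idx), 0, sdz),
                      nrow = nmax - 1)
      z <- apply(steps, 2, cumsum) +
        rep(runif(length(idx), -h, h), each = nmax - 1)
      if (nmax == 2) z <- matrix(z, nrow = 1)
      out <- abs(z) > h
      anyOut <- colSums(out) > 0
      firstOut <- rep(nmax + 1L, length(idx))
      firstOut[anyOut] <- apply(out[, anyOut, drop = FALSE], 2,
                                which.max) + 1L
      nf[idx] <- pmax(1L, pmin(nb[idx], firstOut - 1L))
    }
  }
  ## xy Brownian walks with grouped cumulative sums
  total <- sum(nf)
  id <- rep(seq_len(n), nf)
  frame <- sequence(nf)
  rowState <- if (stateSwitching)
    sample.int(nstate, total, replace = TRUE,
               prob = params$fractions) else state[id]
  sdrow <- sqrt(2 * params$D[rowState] * dt)
  startIdx <- cumsum(c(1, nf[-n]))
  mkAxis <- function() {
    stp <- rnorm(total, 0, sdrow)
    stp[startIdx] <- 0
    cs <- cumsum(stp)
    cs - rep(cs[startIdx], nf) + rnorm(total, 0, params$sigmaLoc)
  }
  tracks <- data.frame(trajectory_id = id, frame = frame,
                       t_s = (frame - 1) * dt, x_um = mkAxis(),
                       y_um = mkAxis())
  ts <- TrajectorySet(tracks, frameInterval = dt,
                      sigmaLoc = params$sigmaLoc, halfDepth = h)
  attr(ts, "trueState") <- state
  ts
}

#' Simulate a FRAP recovery curve
#'
#' Reaction-dominant recovery: prebleach baseline 1 for
#' \code{prebleachFrames} frames, then
#' 1 - bleachDepth * sum(w_m exp(-kOff_m t)) with t measured from the
#' bleach, plus i.i.d. Gaussian noise.
#'
#' @param params A \code{\link{kineticParams}} (uses kOff, kOffWeights).
#' @param nFrames Total frames (default 240).
#' @param noiseSd Gaussian noise s.d. (fraction of baseline; >= 0).
#' @param prebleachFrames Frames before the bleach pulse (default 20).
#' @param frameIntervalS Frame interval (s, default 0.25).
#' @param bleachDepth Fraction bleached (C_eq; default 0.3).
#' @param seed Integer seed.
#' @return data.frame (t_s, intensity) with attributes
#'   \code{bleachFrame} and \code{frameInterval}; t_s is measured from
#'   acquisition start, the bleach occurs after frame
#'   \code{prebleachFrames}.
#' @export
simulateFrap <- function(params, nFrames = 240L, noiseSd = 0,
                         prebleachFrames = 20L, frameIntervalS = 0.25,
                         bleachDepth = 0.3, seed = 1L) {
  stopifnot(inherits(params, "kineticParams"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (nFrames <= prebleachFrames)
    stop("nFrames must exceed prebleachFrames")
  set.seed(seed)
  tAll <- (seq_len(nFrames) - 1) * frameIntervalS
  tPost <- tAll[(prebleachFrames + 1):nFrames] -
    tAll[prebleachFrames]
  recov <- 1 - bleachDepth *
    colSums(params$kOffWeights * exp(-outer(params$kOff, tPost)))
  intensity <- c(rep(1, prebleachFrames), recov)
  if (noiseSd > 0)
    intensity <- intensity + rnorm(nFrames, 0, noiseSd)
  structure(data.frame(t_s = tAll, intensity = intensity),
            bleachFrame = prebleachFrames,
            frameInterval = frameIntervalS)
}

#' Simulate binding durations across exposure times (slow-SPT)
#'
#' Durations are drawn from the dissociation-rate mixture with apparent
#' rate k_app = k_off + kBleach * (exposure / frameInterval) per
#' component (photobleaching accelerates apparent unbinding in
#' proportion to photon dose), then discretized to frames of length
#' \code{exposure} (continuous acquisition).
#'
#' @param params A \code{\link{kineticParams}}; \code{frameInterval}
#'   here is the reference frame time for the bleach-rate scaling.
#' @param exposures Exposure times in seconds (within [0.05, 0.25] by
#'   convention for slow tracking).
#' @param nPer Durations per exposure.
#' @param seed Integer seed.
#' @return data.frame (exposure_s, frames, duration_s).
#' @export
simulateBindingDurations <- function(params, exposures = 0.1,
                                     nPer = 1000L, seed = 1L) {
  stopifnot(inherits(params, "kineticParams"))
  if (length(exposures) == 0) stop("exposures must be non-empty")
  set.seed(seed)
  out <- lapply(exposures, function(ex) {
    if (nPer <= 0)
      return(data.frame(exposure_s = numeric(0), frames = integer(0),
                        duration_s = numeric(0)))
    comp <- sample.int(length(params$kOff), nPer, replace = TRUE,
                       prob = params$kOffWeights)
    kApp <- params$kOff[comp] +
      params$kBleach * (ex / params$frameInterval)
    t <- rexp(nPer, kApp)
    frames <- floor(t / ex) + 1L
    data.frame(exposure_s = ex, frames = frames,
               duration_s = frames * ex)
  })
  do.call(rbind, out)
}

#' Simulate gene expression linked to planted loop strength
#'
#' One gene per promoter anchor (the promoter anchor of EP dots, both
#' anchors of PP dots), TSS at the anchor midpoint, strand uniform.
#' log-expression = intercept + linkSlope * log(amplitude) + noise.
#'
#' @param truth Ground-truth list from \code{\link{simulateContactMap}}.
#' @param linkSlope Link between log amplitude and log TPM.
#' @param noiseSd Noise s.d. on log TPM.
#' @param intercept Baseline log TPM (default log(10)).
#' @param geneLength Gene length (bp, default 20000).
#' @param seed Integer seed.
#' @return data.frame (name, tss, tes, strand, tpm, deg_status,
#'   loop_index, amplitude); empty with a warning if the truth has no
#'   promoter anchors.
#' @export
simulateExpression <- function(truth, linkSlope = 1, noiseSd = 0.1,
                               intercept = log(10), geneLength = 2e4,
                               seed = 1L) {
  loops <- truth$loops
  cls <- loopClass(loops)
  promoters <- list()
  k <- 0
  for (i in seq_along(loops)) {
    if (cls[i] == "EP") {
      promoters[[k <- k + 1]] <- list(anchor = anchorTwo(loops)[i],
                                      loop = i)
    } else if (cls[i] == "PP") {
      promoters[[k <- k + 1]] <- list(anchor = anchorOne(loops)[i],
                                      loop = i)
      promoters[[k <- k + 1]] <- list(anchor = anchorTwo(loops)[i],
                                      loop = i)
    }
  }
  if (!length(promoters)) {
    warning("no promoter anchors in truth; empty gene table")
    return(data.frame(name = character(0), tss = numeric(0),
                      tes = numeric(0), strand = character(0),
                      tpm = numeric(0), deg_status = character(0),
                      loop_index = integer(0), amplitude = numeric(0)))
  }
  set.seed(seed)
  li <- vapply(promoters, function(p) p$loop, 1L)
  tss <- vapply(promoters, function(p)
    (start(p$anchor) + end(p$anchor)) / 2, 1)
  strand <- sample(c("+", "-"), length(tss), replace = TRUE)
  tes <- ifelse(strand == "+", tss + geneLength, tss - geneLength)
  amp <- truth$amplitude[li]
  ltpm <- intercept + linkSlope * log(amp) +
    rnorm(length(tss), 0, noiseSd)
  data.frame(name = paste0("gene", seq_along(tss)), tss = tss,
             tes = tes, strand = strand, tpm = exp(ltpm),
             deg_status = "no", loop_index = li, amplitude = amp)
}
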