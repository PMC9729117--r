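## Single-molecule kinetics: jump-length diffusion-state mixtures,
## slow-tracking survival curves, reaction-dominant FRAP and
## target-search inference.

## diffusion-state bin edges (um^2/s): bound < 0.1, slow 0.1-2, fast > 2
.dBinEdges <- c(0.1, 2)

#' Compute jump lengths from trajectories
#'
#' Euclidean displacements for lags 1..maxLag; jumps spanning frame
#' gaps are excluded (frame difference must equal the lag).
#'
#' @param x A \linkS4class{TrajectorySet}.
#' @param maxLag Maximum lag (frames, default 1).
#' @return data.frame: trajectory_id, lag, jump_um.
#' @export
computeJumpLengths <- function(x, maxLag = 1L) {
  d <- x@tracks
  if (nrow(d) == 0) stop("empty trajectory set")
  d <- d[order(d$trajectory_id, d$frame), ]
  out <- vector("list", maxLag)
  for (lag in seq_len(maxLag)) {
    i1 <- seq_len(nrow(d) - lag)
    i2 <- i1 + lag
    ok <- d$trajectory_id[i1] == d$trajectory_id[i2] &
      (d$frame[i2] - d$frame[i1]) == lag
    out[[lag]] <- data.frame(
      trajectory_id = d$trajectory_id[i1][ok], lag = lag,
      jump_um = sqrt((d$x_um[i2] - d$x_um[i1])[ok]^2 +
                       (d$y_um[i2] - d$y_um[i1])[ok]^2))
  }
  do.call(rbind, out)
}

## probability that a molecule starting uniform in the detection slab
## is still inside after one frame of axial diffusion
.pObserved <- function(D, dt, h) {
  if (!is.finite(h)) return(1)
  sdz <- sqrt(2 * D * dt)
  if (sdz <= 0) return(1)
  f <- function(z0) pnorm((h - z0) / sdz) - pnorm((-h - z0) / sdz)
  integrate(f, -h, h)$value / (2 * h)
}

## EM for a trajectory-level mixture: each trajectory carries one
## state; its jumps are i.i.d. exponential in r^2 with component mean
## mu_m = 4 (sigma^2 + D_m dt). Only the per-trajectory sufficient
## statistics (sum of r^2, jump count) enter each iteration.
.emTrajMixture <- function(R, m, mu0, frac0, muMin, maxIter = 1000,
                           tol = 1e-10) {
  K <- length(mu0)
  mu <- pmax(mu0, muMin)
  frac <- frac0 / sum(frac0)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    A <- -outer(R, 1 / mu) - outer(m, log(mu)) +
      rep(log(frac), each = length(R))
    amax <- apply(A, 1, max)
    W <- exp(A - amax)
    rs <- rowSums(W)
    newLL <- sum(amax + log(rs))
    g <- W / rs
    cs <- colSums(g)
    frac <- cs / length(R)
    mu <- pmax(colSums(g * R) / colSums(g * m), muMin)
    if (is.finite(ll) && abs(newLL - ll) < tol * (abs(newLL) + 1))
      break
    ll <- newLL
  }
  list(mu = mu, frac = frac, logLik = newLL)
}

## weighted EM for a mixture of exponentials on squared displacements,
## component mean mu_m = 4 (sigma^2 + D_m dt), D_m >= 0
.emExpMixture <- function(r2, wt, mu0, frac0, muMin, maxIter = 300,
                          tol = 1e-8) {
  K <- length(mu0)
  mu <- pmax(mu0, muMin)
  frac <- frac0 / sum(frac0)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(K), function(m)
      frac[m] * exp(-r2 / mu[m]) / mu[m], numeric(length(r2)))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    newLL <- sum(wt * log(tot))
    gamma <- dens / tot
    W <- colSums(wt * gamma)
    frac <- W / sum(W)
    mu <- pmax(colSums(wt * gamma * r2) / W, muMin)
    if (is.finite(ll) && abs(newLL - ll) < tol * (abs(newLL) + 1)) {
      ll <- newLL
      break
    }
    ll <- newLL
  }
  ## final log-likelihood at the returned parameters
  dens <- vapply(seq_len(K), function(m)
    frac[m] * exp(-r2 / mu[m]) / mu[m], numeric(length(r2)))
  tot <- rowSums(dens)
  tot[tot <= 0] <- .Machine$double.xmin
  list(mu = mu, frac = frac, logLik = sum(wt * log(tot)))
}

#' Fit a diffusion-state mixture to jump lengths
#'
#' Maximum-likelihood fit of the lag-1 squared-displacement mixture.
#' The jump-length density for state m is
#' r / (2 (sigma^2 + D_m dt)) * exp(-r^2 / (4 (sigma^2 + D_m dt))),
#' i.e. squared displacements are exponential with mean
#' 4 (sigma^2 + D_m dt). With \code{method = "trajectory"} (the
#' default) each trajectory is treated as a single molecule in one
#' state and its jumps enter the likelihood jointly, so the fractions
#' estimate molecule occupancies directly; \code{method = "jump"}
#' fits the marginal jump mixture instead, optionally weighting each
#' trajectory equally (each jump by 1/n_jumps). When the axial
#' detection half-depth is known, fractions are reweighted by the
#' inverse single-frame observation probability of each state
#' (molecules whose first axial step leaves the detection slab are
#' never observed, a state-dependent loss).
#'
#' @param x A \linkS4class{TrajectorySet} or a jump data.frame from
#'   \code{\link{computeJumpLengths}} (lag-1 rows used).
#' @param nStates 2 or 3.
#' @param sigmaLoc Localization error (um); default taken from the
#'   trajectory set. Ignored when \code{sigmaFree}.
#' @param dt Frame interval (s); default from the trajectory set.
#' @param sigmaFree Estimate the localization error as a free
#'   parameter (direct likelihood optimization; default FALSE).
#' @param halfDepth Axial detection half-depth (um) for the
#'   observation-probability reweighting; default from the trajectory
#'   set; Inf disables it.
#' @param method "trajectory" (per-molecule likelihood, default) or
#'   "jump" (marginal jump mixture).
#' @param weightPerMolecule For \code{method = "jump"}: weight
#'   trajectories equally (default TRUE).
#' @param nStarts Multi-starts (default 10).
#' @param seed Seed for the start grid.
#' @return A \linkS4class{StateMixtureFit}.
#' @export
fitDiffusionMixture <- function(x, nStates = 3, sigmaLoc = NULL,
                                dt = NULL, sigmaFree = FALSE,
                                halfDepth = NULL,
                                method = c("trajectory", "jump"),
                                weightPerMolecule = TRUE,
                                nStarts = 10L, seed = 1L) {
  method <- match.arg(method)
  if (!nStates %in% c(2, 3)) stop("nStates must be 2 or 3")
  if (inherits(x, "TrajectorySet")) {
    jumps <- computeJumpLengths(x, maxLag = 1L)
    if (is.null(sigmaLoc)) sigmaLoc <- x@sigmaLoc
    if (is.null(dt)) dt <- x@frameInterval
    if (is.null(halfDepth)) halfDepth <- x@halfDepth
  } else {
    jumps <- x[x$lag == 1L, ]
    if (is.null(sigmaLoc) || is.null(dt))
      stop("sigmaLoc and dt are required with a jump table")
    if (is.null(halfDepth)) halfDepth <- Inf
  }
  if (nrow(jumps) == 0) stop("no lag-1 jumps")
  if (nStates == 3 && nrow(jumps) < 5000)
    warning("3-state fit with fewer than 5,000 jumps")
  r2 <- jumps$jump_um^2
  if (method == "trajectory") {
    R <- as.numeric(rowsum(r2, jumps$trajectory_id))
    m <- as.numeric(rowsum(rep(1, length(r2)), jumps$trajectory_id))
  } else {
    wt <- if (weightPerMolecule) {
      nj <- table(jumps$trajectory_id)
      1 / as.numeric(nj[as.character(jumps$trajectory_id)])
    } else rep(1, length(r2))
  }
  ## start grid: canonical bound/slow/fast guesses plus random
  ## log-uniform draws; multi-start EM at a given sigma
  set.seed(seed)
  canonical <- list(c(0.005, 0.5, 5)[seq_len(nStates)],
                    c(0.01, 1, 8)[seq_len(nStates)])
  starts <- c(canonical, lapply(seq_len(max(0, nStarts - 2)),
    function(b) sort(10^runif(nStates, -3, 1.2))))
  runEM <- function(sig) {
    muMin <- max(4 * sig^2, .Machine$double.eps)
    best <- NULL
    for (st in starts) {
      mu0 <- pmax(4 * (sig^2 + st * dt), muMin)
      fit <- if (method == "trajectory")
        .emTrajMixture(R, m, mu0, rep(1 / nStates, nStates), muMin)
      else .emExpMixture(r2, wt, mu0, rep(1 / nStates, nStates),
                         muMin)
      if (is.null(best) || fit$logLik > best$logLik ||
          (fit$logLik == best$logLik &&
           min(fit$mu) < min(best$mu)))
        best <- fit
    }
    best
  }
  if (sigmaFree) {
    ## profile likelihood over the localization error
    upper <- sqrt(quantile(r2, 0.5)) / 2
    opt <- optimize(function(s) -runEM(s)$logLik, c(0, upper))
    sigmaHat <- opt$minimum
    best <- runEM(sigmaHat)
  } else {
    sigmaHat <- sigmaLoc
    best <- runEM(sigmaLoc)
  }
  if (is.null(best) || !is.finite(best$logLik))
    stop("mixture fit did not converge over ", length(starts),
         " starts")
  D <- pmax(0, (best$mu / 4 - sigmaHat^2) / dt)
  o <- order(D)
  D <- D[o]
  frac <- best$frac[o]
  ## single-frame defocalization reweighting to molecule occupancies
  corrected <- FALSE
  if (is.finite(halfDepth)) {
    pObs <- vapply(D, .pObserved, 1, dt = dt, h = halfDepth)
    frac <- frac / pObs
    frac <- frac / sum(frac)
    corrected <- TRUE
  }
  binned <- c(bound = sum(frac[D < .dBinEdges[1]]),
              slow = sum(frac[D >= .dBinEdges[1] &
                                D <= .dBinEdges[2]]),
              fast = sum(frac[D > .dBinEdges[2]]))
  new("StateMixtureFit", fractions = frac, D = D,
      sigmaLoc = sigmaHat, logLik = best$logLik,
      nJumps = nrow(jumps), binned = binned,
      defocalizationCorrected = corrected)
}

## geometric MLE for frame counts m >= minFrames:
## m - minFrames ~ Geometric, survival per frame q = exp(-k * frameS)
.geomRate <- function(m, minFrames, frameS) {
  mbar <- mean(m - minFrames)
  q <- mbar / (1 + mbar)
  if (q <= 0) stop("all durations at the minimum-duration filter; ",
                   "cannot fit a rate")
  -log(q) / frameS
}

## weighted EM for a 2-component geometric mixture on m >= minFrames
.geomMixture2 <- function(m, minFrames, frameS, nStarts = 10,
                          seed = 1) {
  set.seed(seed)
  x <- m - minFrames
  fit1 <- function(q0, w0) {
    q <- q0
    w <- w0
    ll <- -Inf
    for (it in 1:500) {
      d1 <- w * (1 - q[1]) * q[1]^x
      d2 <- (1 - w) * (1 - q[2]) * q[2]^x
      tot <- d1 + d2
      tot[tot <= 0] <- .Machine$double.xmin
      newLL <- sum(log(tot))
      g <- d1 / tot
      w <- mean(g)
      q[1] <- sum(g * x) / sum(g * (x + 1))
      q[2] <- sum((1 - g) * x) / sum((1 - g) * (x + 1))
      q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
      if (is.finite(ll) && abs(newLL - ll) < 1e-12 * abs(newLL))
        break
      ll <- newLL
    }
    list(q = q, w = w, logLik = newLL)
  }
  qbar <- mean(x) / (1 + mean(x))
  starts <- c(list(list(q = pmin(c(qbar * 0.7, min(qbar * 1.2,
                                                   0.999)), 0.999),
                        w = 0.5)),
              lapply(seq_len(nStarts - 1), function(b)
                list(q = sort(runif(2, 0.3, 0.999)),
                     w = runif(1, 0.1, 0.9))))
  best <- NULL
  for (s in starts) {
    f <- fit1(s$q, s$w)
    if (is.null(best) || f$logLik > best$logLik) best <- f
  }
  k <- -log(best$q) / frameS
  o <- order(k)
  list(rates = k[o], weights = c(best$w, 1 - best$w)[o],
       logLik = best$logLik)
}

#' Fit binding-duration survival curves (slow-SPT)
#'
#' Maximum-likelihood exponential (or two-exponential) fit of
#' discretized binding durations at each exposure, restricted to
#' durations of at least \code{minFrames} frames, with photobleaching
#' correction: either subtraction of a known per-frame bleach rate
#' (k_off = k_app - kB * exposure / frameInterval per component) or,
#' with two or more exposures, linear extrapolation of the apparent
#' rate to zero exposure.
#'
#' @param durations data.frame from
#'   \code{\link{simulateBindingDurations}} (exposure_s, frames).
#' @param model "1-exp" or "2-exp".
#' @param kB Known photobleach rate per frame, or NULL to extrapolate.
#' @param frameInterval Reference frame time (s) for the bleach-rate
#'   scaling; defaults to the smallest exposure.
#' @param minFrames Minimum-duration filter (frames, default 2).
#' @param nStarts Multi-starts for the 2-exp fit.
#' @param seed Seed for the start grid.
#' @return A \linkS4class{SurvivalFit}. With a single exposure and
#'   unknown kB the apparent rate is returned, flagged uncorrected.
#' @export
fitSurvival <- function(durations, model = c("1-exp", "2-exp"),
                        kB = NULL, frameInterval = NULL,
                        minFrames = 2L, nStarts = 10L, seed = 1L) {
  model <- match.arg(model)
  if (nrow(durations) == 0) stop("empty duration set")
  exposures <- sort(unique(durations$exposure_s))
  if (is.null(frameInterval)) frameInterval <- min(exposures)
  perExp <- lapply(exposures, function(ex) {
    m <- durations$frames[durations$exposure_s == ex]
    m <- m[m >= minFrames]
    if (length(m) == 0)
      stop("no durations pass the ", minFrames,
           "-frame minimum-duration filter at exposure ", ex)
    if (length(m) < 100)
      warning("fewer than 100 durations at exposure ", ex)
    if (model == "1-exp")
      list(rates = .geomRate(m, minFrames, ex), weights = 1)
    else .geomMixture2(m, minFrames, ex, nStarts = nStarts,
                       seed = seed)
  })
  appRates <- vapply(perExp, function(f) f$rates[1], 1)
  if (!is.null(kB)) {
    ref <- perExp[[1]]
    corr <- kB * exposures[1] / frameInterval
    rates <- pmax(ref$rates - corr, .Machine$double.eps)
    fit <- new("SurvivalFit", rates = rates,
               weights = ref$weights, kB = kB,
               apparentRates = appRates, exposures = exposures,
               residenceTimes = 1 / rates, corrected = TRUE)
  } else if (length(exposures) >= 2) {
    if (model == "2-exp")
      stop("zero-exposure extrapolation supports the 1-exp model; ",
           "supply kB for mixture correction")
    k0 <- unname(coef(lm(appRates ~ exposures))[1])
    k0 <- max(k0, .Machine$double.eps)
    fit <- new("SurvivalFit", rates = k0, weights = 1,
               kB = NA_real_, apparentRates = appRates,
               exposures = exposures, residenceTimes = 1 / k0,
               corrected = TRUE)
  } else {
    warning("single exposure and unknown bleach rate: returning ",
            "apparent (uncorrected) rate")
    ref <- perExp[[1]]
    fit <- new("SurvivalFit", rates = ref$rates,
               weights = ref$weights, kB = NA_real_,
               apparentRates = appRates, exposures = exposures,
               residenceTimes = 1 / ref$rates, corrected = FALSE)
  }
  fit
}

#' Fit a reaction-dominant FRAP recovery curve
#'
#' Normalizes to the prebleach baseline (with linear detrending if the
#' baseline drifts beyond 5 percent), then least-squares fits
#' 1 - sum(A_m exp(-k_m t)) to the postbleach recovery, t measured
#' from the bleach. Residence times are 1/k_m; the two-binding-state
#' model also reports the slow-recovering fraction.
#'
#' @param curve data.frame (t_s, intensity), e.g. from
#'   \code{\link{simulateFrap}}.
#' @param model "one-binding-state" or "two-binding-state".
#' @param prebleachFrames Frames before the bleach; default from the
#'   curve's \code{bleachFrame} attribute, else 20.
#' @return A \linkS4class{FRAPFit}.
#' @export
fitFrap <- function(curve, model = c("one-binding-state",
                                     "two-binding-state"),
                    prebleachFrames = NULL) {
  model <- match.arg(model)
  if (is.null(prebleachFrames))
    prebleachFrames <- attr(curve, "bleachFrame")
  if (is.null(prebleachFrames)) prebleachFrames <- 20L
  if (nrow(curve) <= prebleachFrames + 3)
    stop("too few postbleach frames")
  pre <- curve$intensity[seq_len(prebleachFrames)]
  tPre <- curve$t_s[seq_len(prebleachFrames)]
  dr <- lm(pre ~ tPre)
  drift <- abs(coef(dr)[2]) * (max(tPre) - min(tPre)) / mean(pre)
  y <- curve$intensity
  if (is.finite(drift) && drift > 0.05) {
    warning("prebleach baseline drift beyond 5%; detrending linearly")
    y <- y / predict(dr, newdata = data.frame(tPre = curve$t_s))
    base <- 1
  } else base <- mean(pre)
  y <- y / base
  post <- (prebleachFrames + 1):nrow(curve)
  t <- curve$t_s[post] - curve$t_s[prebleachFrames]
  yp <- y[post]
  depth <- 1 - min(yp[seq_len(min(5, length(yp)))])
  if (depth < 0.02) stop("no recovery signal")
  a0 <- 1 - yp[1]
  khalf <- {
    half <- which(yp >= 1 - a0 / 2)[1]
    if (is.na(half)) 1 / max(t) else log(2) / t[half]
  }
  fitFun <- function(formula, start) {
    tryCatch(minpack.lm::nlsLM(formula,
                               data = data.frame(t = t, y = yp),
                               start = start,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             error = function(e) NULL)
  }
  if (model == "one-binding-state") {
    fit <- fitFun(y ~ 1 - A * exp(-k * t),
                  list(A = a0, k = khalf))
    if (is.null(fit)) stop("FRAP fit did not converge")
    co <- coef(fit)
    rates <- unname(co["k"])
    amps <- unname(co["A"])
  } else {
    fit <- fitFun(y ~ 1 - A1 * exp(-k1 * t) - A2 * exp(-k2 * t),
                  list(A1 = 0.85 * a0, k1 = khalf,
                       A2 = 0.15 * a0, k2 = khalf / 5))
    if (is.null(fit)) stop("FRAP fit did not converge")
    co <- coef(fit)
    o <- order(c(co["k1"], co["k2"]), decreasing = TRUE)
    rates <- unname(c(co["k1"], co["k2"]))[o]
    amps <- unname(c(co["A1"], co["A2"]))[o]
  }
  new("FRAPFit", model = model, rates = rates, amplitudes = amps,
      plateau = 1, residSE = sqrt(mean(residuals(fit)^2)),
      residenceTimes = 1 / rates)
}

#' Infer target-search kinetics
#'
#' Combines the bound fraction with the residence time:
#' k_off = 1/tau_res, k*_on = k_off * F_bound / (1 - F_bound),
#' tau_search = 1/k*_on = tau_res * (1 - F_bound) / F_bound. These
#' satisfy F_bound = k*_on / (k*_on + k_off) exactly.
#'
#' @param fBound Bound fraction, strictly inside (0, 1).
#' @param tauRes Residence time (s, > 0).
#' @return A \linkS4class{SearchKinetics}.
#' @export
inferSearchKinetics <- function(fBound, tauRes) {
  if (fBound <= 0 || fBound >= 1)
    stop("F_bound must be strictly inside (0, 1): search time ",
         "undefined at the boundary")
  if (tauRes <= 0) stop("tauRes must be positive")
  kOff <- 1 / tauRes
  kOn <- kOff * fBound / (1 - fBound)
  new("SearchKinetics", fBound = fBound, tauRes = tauRes, kOn = kOn,
      tauSearch = 1 / kOn)
}

#' Compare search kinetics between two conditions
#'
#' Reports the fractional k*_on change, the search-time fold-change
#' (which equals 1 / (1 - fractional k*_on decrease)) and the
#' residence-time fold-change.
#'
#' @param kinUT,kinIAA \linkS4class{SearchKinetics} for the untreated
#'   and depleted conditions.
#' @return List: konDecrease (fractional), searchTimeFold,
#'   residenceFold, searchTimes (named, s).
#' @export
compareConditions <- function(kinUT, kinIAA) {
  dec <- 1 - kinIAA@kOn / kinUT@kOn
  list(konDecrease = dec,
       searchTimeFold = kinIAA@tauSearch / kinUT@tauSearch,
       residenceFold = kinIAA@tauRes / kinUT@tauRes,
       searchTimes = c(UT = kinUT@tauSearch,
                       IAA = kinIAA@tauSearch))
}

#' Search-time fold-change implied by a k*_on decrease
#'
#' At constant residence time, a fractional decrease d in the pseudo
#' association rate lengthens the search time by 1 / (1 - d).
#'
#' @param konDecrease Fractional k*_on decrease in [0, 1).
#' @return Fold-change of the search time.
#' @export
searchTimeFoldChange <- function(konDecrease) {
  if (any(konDecrease >= 1)) stop("konDecrease must be below 1")
  1 / (1 - konDecrease)
}

#' Bootstrap confidence interval for search kinetics
#'
#' Resamples trajectories with replacement, refits the diffusion
#' mixture and recomputes the search kinetics at a fixed residence
#' time.
#'
#' @param x A \linkS4class{TrajectorySet}.
#' @param tauRes Residence time (s).
#' @param B Bootstrap replicates (default 20).
#' @param seed Seed.
#' @param ... Passed to \code{\link{fitDiffusionMixture}}.
#' @return List: tauSearch (point), ci (2.5/97.5 percent quantiles),
#'   boot (replicate values).
#' @export
bootstrapSearchKinetics <- function(x, tauRes, B = 20L, seed = 1L,
                                    ...) {
  fit <- fitDiffusionMixture(x, seed = seed, ...)
  point <- inferSearchKinetics(boundFraction(fit), tauRes)
  d <- x@tracks
  ids <- unique(d$trajectory_id)
  byId <- split(d, d$trajectory_id)
  set.seed(seed)
  boot <- vapply(seq_len(B), function(b) {
    pick <- sample(as.character(ids), length(ids), replace = TRUE)
    db <- do.call(rbind, lapply(seq_along(pick), function(i) {
      di <- byId[[pick[i]]]
      di$trajectory_id <- i
      di
    }))
    tsb <- TrajectorySet(db, frameInterval = x@frameInterval,
                         sigmaLoc = x@sigmaLoc,
                         halfDepth = x@halfDepth)
    fb <- fitDiffusionMixture(tsb, seed = seed + b, ...)
    inferSearchKinetics(boundFraction(fb), tauRes)@tauSearch
  }, 1)
  list(tauSearch = point@tauSearch,
       ci = quantile(boot, c(0.025, 0.975)), boot = boot)
}
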