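## Shared builders for the test suite. Everything here is generated in
## code from fixed seeds; no fixture files.

library(GenomicRanges)

## A small decay-only map (no TADs, no dots).
plainMap <- function(chromLength = 1e6, binSize = 1e4, depth = 2e6,
                     alpha = 1, seed = 1) {
  cfg <- simConfig(chromLength, binSize, decayExponent = alpha,
                   depth = depth)
  simulateContactMap(cfg, seed = seed)
}

## A map with regular TADs and insulated boundaries.
tadMap <- function(chromLength = 4e6, binSize = 2e4, tadBp = 4e5,
                   beta = 1.5, gamma = 0.3, depth = 1.6e7, seed = 7) {
  ti <- cbind(seq(0, chromLength - tadBp, by = tadBp),
              seq(tadBp, chromLength, by = tadBp))
  cfg <- simConfig(chromLength, binSize, decayExponent = 1,
                   tadIntervals = ti, intraTadFactor = beta,
                   boundaryInsulation = gamma, depth = depth)
  simulateContactMap(cfg, seed = seed)
}

## Regularly spaced dots of one class starting at `lo` bp.
dotBlock <- function(n, cls, lo, spacing = 4e4, binSize = 2e3,
                     offsets = seq(1.2e5, 2.4e5, by = 2e3),
                     amplitude = 3, seed = 42) {
  set.seed(seed)
  a1 <- lo + (seq_len(n) - 1) * spacing
  off <- sample(offsets, n, replace = TRUE)
  data.frame(anchor1 = a1 + binSize / 2,
             anchor2 = a1 + off + binSize / 2,
             amplitude = amplitude, sigma = 1.5, class = cls)
}

## Balanced O/E matrix from a simulated map.
toOE <- function(sim) observedOverExpected(balanceICE(sim$map))

## Hand-built O/E BinnedContactMatrix from a plain matrix.
oeMatrix <- function(M, binSize = 1e4) {
  BinnedContactMatrix(M, chrom = "chrS", binSize = binSize,
                      weights = rep(1, nrow(M)),
                      normalization = "oe")
}

## Independent ICE fixed-point oracle: iterate the row-sum update to
## machine precision on an unmasked matrix and rescale like the
## implementation (mean corrected row sum = 1).
iceOracle <- function(C, iters = 100000) {
  b <- rep(1, nrow(C))
  for (it in seq_len(iters)) {
    s <- as.vector(C %*% (1 / b)) / b
    b <- b * s / mean(s)
    if (var(s) / mean(s)^2 < 1e-28) break
  }
  w <- 1 / b
  bal <- outer(w, w) * C
  w / sqrt(mean(rowSums(bal)))
}

## Brute-force insulation diamond mean for bin i, window w (bins).
diamondOracle <- function(B, i, w) {
  n <- nrow(B)
  if (i < w || i + w > n) return(NA_real_)
  vals <- c()
  for (r in (i - w + 1):i) for (cc in (i + 1):(i + w))
    vals <- c(vals, B[r, cc])
  mean(vals, na.rm = TRUE)
}

## Independent centre/corner loop-score arithmetic.
scoreOracle <- function(M, i, j, w) {
  box <- function(ci, cj) mean(M[(ci - 1):(ci + 1), (cj - 1):(cj + 1)],
                               na.rm = TRUE)
  centre <- box(i, j)
  bg <- mean(c(M[(i - w - 1):(i - w + 1), (j - w - 1):(j - w + 1)],
               M[(i - w - 1):(i - w + 1), (j + w - 1):(j + w + 1)],
               M[(i + w - 1):(i + w + 1), (j - w - 1):(j - w + 1)],
               M[(i + w - 1):(i + w + 1), (j + w - 1):(j + w + 1)]),
             na.rm = TRUE)
  centre / bg
}

## Exponential-mixture log-likelihood at given parameters (jump level).
expMixLL <- function(r2, mu, frac) {
  dens <- sapply(seq_along(mu), function(m)
    frac[m] * exp(-r2 / mu[m]) / mu[m])
  sum(log(rowSums(dens)))
}
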