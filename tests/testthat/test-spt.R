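test_that("jump lengths match direct enumeration with frame gaps", {
  ## 10 short trajectories, one with a frame gap
  d <- data.frame(
    trajectory_id = rep(1:10, each = 3),
    frame = rep(1:3, 10),
    x_um = as.numeric(1:30), y_um = 0)
  d$t_s <- (d$frame - 1) * 0.01
  d$frame[3] <- 5  # gap in trajectory 1
  ts <- TrajectorySet(d, frameInterval = 0.01)
  j1 <- computeJumpLengths(ts, maxLag = 1)
  ## 9 trajectories x 2 jumps + 1 valid jump in trajectory 1
  expect_equal(nrow(j1), 19)
  expect_true(all(j1$jump_um == 1))
  j2 <- computeJumpLengths(ts, maxLag = 2)
  n2 <- sum(j2$lag == 2)
  expect_equal(n2, 9)  # trajectory 1 has no valid lag-2 pair
  expect_true(all(j2$jump_um[j2$lag == 2] == 2))
})

test_that("EM log-likelihood matches a dense grid-search MLE", {
  set.seed(7)
  n <- 500
  st <- sample(1:2, n, TRUE, prob = c(0.4, 0.6))
  mu <- c(0.002, 0.03)[st]
  r2 <- rexp(n, 1 / mu)
  jumps <- data.frame(trajectory_id = seq_len(n), lag = 1L,
                      jump_um = sqrt(r2))
  fit <- fitDiffusionMixture(jumps, nStates = 2, sigmaLoc = 0,
                             dt = 0.0075, method = "jump",
                             weightPerMolecule = FALSE)
  grid <- expand.grid(
    m1 = 10^seq(log10(5e-4), log10(0.1), length.out = 60),
    m2 = 10^seq(log10(5e-4), log10(0.1), length.out = 60),
    f = seq(0.05, 0.95, by = 0.05))
  grid <- grid[grid$m1 < grid$m2, ]
  gridLL <- max(vapply(seq_len(nrow(grid)), function(i)
    expMixLL(r2, c(grid$m1[i], grid$m2[i]),
             c(grid$f[i], 1 - grid$f[i])), 1))
  expect_gte(fit@logLik, gridLL - 1e-3)
})

test_that("the mixture fit recovers three-state occupancies", {
  kp <- kineticParams()
  ts <- simulateTrajectories(kp, n = 20000, seed = 1)
  fit <- fitDiffusionMixture(ts)
  expect_true(fit@defocalizationCorrected)
  expect_equal(unname(stateFractions(fit)),
               unname(kp$fractions), tolerance = 0.03)
  expect_equal(diffusionCoefficients(fit)[2:3], kp$D[2:3],
               tolerance = 0.15)
  expect_lt(diffusionCoefficients(fit)[1], 0.1)
  expect_equal(boundFraction(fit),
               sum(stateFractions(fit)[diffusionCoefficients(fit) <
                                         0.1]))
})

test_that("mixture fitting warns on small samples and checks inputs", {
  kp <- kineticParams()
  ts <- simulateTrajectories(kp, n = 300, seed = 2)
  expect_warning(fitDiffusionMixture(ts), "5,000")
  j <- computeJumpLengths(ts)
  expect_error(fitDiffusionMixture(j), "sigmaLoc and dt")
  expect_error(fitDiffusionMixture(ts, nStates = 4), "2 or 3")
})

test_that("free localization error is recovered by profile likelihood", {
  kp <- kineticParams(fractions = c(bound = 0.5, slow = 0.5),
                      D = c(0.005, 0.5), halfDepth = Inf,
                      kBleach = 0.05)
  ts <- simulateTrajectories(kp, n = 4000, seed = 4)
  fit <- suppressWarnings(
    fitDiffusionMixture(ts, nStates = 2, sigmaFree = TRUE))
  expect_equal(fit@sigmaLoc, 0.035, tolerance = 0.25)
})

test_that("survival fitting recovers the residence time without bleaching", {
  kp <- kineticParams(kBleach = 0)
  d <- simulateBindingDurations(kp, exposures = 0.1, nPer = 5000,
                                seed = 1)
  expect_warning(fit <- fitSurvival(d), "uncorrected")
  expect_false(fit@corrected)
  expect_equal(residenceTimes(fit), 13, tolerance = 1 / 13)
})

test_that("apparent rates rise linearly with exposure and extrapolate to k_off", {
  kp <- kineticParams(kOff = 1 / 13, kBleach = 0.01,
                      frameInterval = 0.05)
  d <- simulateBindingDurations(kp, exposures = c(0.05, 0.1, 0.25),
                                nPer = 5000, seed = 2)
  fit <- fitSurvival(d)
  expect_true(fit@corrected)
  expect_true(all(diff(fit@apparentRates) > 0))
  ## linearity: apparent rate ~ k_off + kB * exposure / frameInterval
  pred <- 1 / 13 + 0.01 * fit@exposures / 0.05
  expect_equal(fit@apparentRates, pred, tolerance = 0.12)
  expect_equal(fit@rates, 1 / 13, tolerance = 0.1)
})

test_that("known-bleach-rate correction recovers the residence time", {
  kp <- kineticParams(kOff = 1 / 13, kBleach = 0.05,
                      frameInterval = 0.1)
  d <- simulateBindingDurations(kp, exposures = 0.1, nPer = 5000,
                                seed = 3)
  fit <- fitSurvival(d, kB = 0.05)
  expect_equal(residenceTimes(fit), 13, tolerance = 1 / 13)
  ## two-exponential fit resolves a rate mixture
  kp2 <- kineticParams(kOff = c(1 / 10, 1 / 80),
                       kOffWeights = c(0.7, 0.3), kBleach = 0,
                       frameInterval = 0.1)
  d2 <- simulateBindingDurations(kp2, exposures = 0.1, nPer = 20000,
                                 seed = 4)
  fit2 <- fitSurvival(d2, model = "2-exp", kB = 0)
  expect_equal(sort(residenceTimes(fit2)), c(10, 80),
               tolerance = 0.25)
  expect_error(fitSurvival(d2[0, ]), "empty")
})

test_that("FRAP fits recover one- and two-state kinetics", {
  kp <- kineticParams()  # kOff = 1/13
  f1 <- fitFrap(simulateFrap(kp, noiseSd = 0.01, seed = 2))
  expect_equal(residenceTimes(f1), 13, tolerance = 1 / 13)
  ## noiseless two-state curve: both rates exact to within 10%
  kp2 <- kineticParams(kOff = c(1 / 13, 1 / 60),
                       kOffWeights = c(0.85, 0.15))
  f0 <- fitFrap(simulateFrap(kp2, noiseSd = 0, bleachDepth = 1),
                model = "two-binding-state")
  expect_equal(sort(residenceTimes(f0)), c(13, 60), tolerance = 0.1)
  expect_equal(sum(f0@amplitudes), 1, tolerance = 0.01)
  expect_equal(f0@amplitudes[order(residenceTimes(f0))][2], 0.15,
               tolerance = 0.05)
  ## 1% noise over a longer acquisition: both within 15%
  f2 <- fitFrap(simulateFrap(kp2, noiseSd = 0.01, bleachDepth = 1,
                             nFrames = 620, seed = 1),
                model = "two-binding-state")
  expect_equal(sort(residenceTimes(f2)), c(13, 60), tolerance = 0.15)
})

test_that("FRAP fitting detrends drifting baselines and rejects flat curves", {
  kp <- kineticParams()
  fr <- simulateFrap(kp, noiseSd = 0)
  drift <- fr
  ## 3%/s drift: well beyond 5% across the ~5 s prebleach window
  drift$intensity <- drift$intensity * (1 + 0.03 * drift$t_s)
  expect_warning(fd <- fitFrap(drift), "drift")
  expect_equal(residenceTimes(fd), 13, tolerance = 0.1)
  flat <- fr
  flat$intensity <- rep(1, nrow(flat))
  expect_error(fitFrap(flat), "no recovery")
})

test_that("search kinetics follow the steady-state algebra exactly", {
  kin <- inferSearchKinetics(0.31, 13)
  expect_equal(searchTime(kin), 13 * (1 - 0.31) / 0.31)
  ## F_bound = kOn / (kOn + kOff) holds exactly
  expect_equal(pseudoOnRate(kin) /
                 (pseudoOnRate(kin) + 1 / 13), 0.31)
  expect_error(inferSearchKinetics(0, 13), "strictly inside")
  expect_error(inferSearchKinetics(1, 13), "strictly inside")
  expect_error(inferSearchKinetics(0.3, -1), "positive")
})

test_that("condition comparison reports consistent fold-changes", {
  kUT <- inferSearchKinetics(0.31, 13)
  kIA <- inferSearchKinetics(0.22, 13)
  cmp <- compareConditions(kUT, kIA)
  expect_equal(cmp$searchTimeFold,
               searchTimeFoldChange(cmp$konDecrease))
  expect_equal(cmp$residenceFold, 1)
  expect_equal(unname(cmp$searchTimes["IAA"] / cmp$searchTimes["UT"]),
               cmp$searchTimeFold)
  ## a 54% k_on decrease lengthens the search ~2.2-fold
  expect_equal(round(searchTimeFoldChange(0.54), 1), 2.2)
  expect_error(searchTimeFoldChange(1), "below 1")
})

test_that("bootstrap search kinetics brackets the point estimate", {
  kp <- kineticParams()
  ts <- simulateTrajectories(kp, n = 3000, seed = 6)
  bs <- suppressWarnings(
    bootstrapSearchKinetics(ts, tauRes = 13, B = 5))
  expect_equal(length(bs$boot), 5)
  expect_true(bs$ci[1] <= median(bs$boot) &&
                median(bs$boot) <= bs$ci[2])
  expect_true(is.finite(bs$tauSearch) && bs$tauSearch > 0)
})
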