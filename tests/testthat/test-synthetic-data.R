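test_that("simConfig validates its generative parameters", {
  expect_error(simConfig(1e6, 3e3), "divide")
  expect_error(simConfig(1e6, 1e4, decayExponent = 0), "decayExponent")
  expect_error(simConfig(1e6, 1e4, boundaryInsulation = 1.5),
               "boundaryInsulation")
  expect_error(simConfig(1e6, 1e4,
                         tadIntervals = cbind(c(0, 1e5), c(2e5, 3e5))),
               "non-overlapping")
  expect_error(simConfig(1e6, 1e4,
                         dots = data.frame(anchor1 = 1e5, anchor2 = 2e5,
                                           amplitude = 0.5)),
               "amplitude")
})

test_that("contact-map simulation is deterministic in the seed", {
  cfg <- simConfig(5e5, 1e4, depth = 1e5)
  a <- simulateContactMap(cfg, seed = 12)
  b <- simulateContactMap(cfg, seed = 12)
  c <- simulateContactMap(cfg, seed = 13)
  expect_identical(contactCounts(a$map), contactCounts(b$map))
  expect_false(identical(contactCounts(a$map), contactCounts(c$map)))
  expect_true(isSymmetric(contactCounts(a$map)))
})

test_that("simulated decay-only map has the configured exponent", {
  sim <- plainMap(chromLength = 2e6, binSize = 2e3, depth = 5e6,
                  alpha = 1)
  cc <- contactCounts(sim$map)
  d <- abs(row(cc) - col(cc))
  s <- 2:200
  mdiag <- vapply(s, function(k) mean(cc[d == k]), 1)
  slope <- unname(coef(lm(log10(mdiag) ~ log10(s)))[2])
  expect_equal(slope, -1, tolerance = 0.05)
})

test_that("a single planted dot drives APA centre enrichment above 2", {
  dots <- data.frame(anchor1 = 5e5 + 1e3, anchor2 = 7e5 + 1e3,
                     amplitude = 3, sigma = 1.5, class = "EP")
  cfg <- simConfig(2e6, 2e3, dots = dots, depth = 2e7)
  sim <- simulateContactMap(cfg, seed = 2)
  oe <- toOE(sim)
  ap <- apa(oe, sim$truth$loops)
  expect_gt(ap$centerRatio, 2)
  expect_equal(ap$n, 1)
})

test_that("annotations propagate planted classes with peak support", {
  dots <- rbind(
    data.frame(anchor1 = 2e5, anchor2 = 4e5, amplitude = 2,
               sigma = 1.5, class = "cohesin"),
    data.frame(anchor1 = 6e5, anchor2 = 8e5, amplitude = 2,
               sigma = 1.5, class = "EP"),
    data.frame(anchor1 = 1e6, anchor2 = 1.2e6, amplitude = 2,
               sigma = 1.5, class = "polycomb"))
  cfg <- simConfig(2e6, 2e3, dots = dots)
  sim <- simulateContactMap(cfg, seed = 1)
  ann <- simulateAnnotations(sim$truth)
  states <- mcols(stateSegments(ann))$state
  expect_true(all(states %in% chromatinStates()))
  expect_true("CTCF/insulator" %in% states)
  expect_true("strong enhancer" %in% states)
  expect_true("active promoter" %in% states)
  expect_true("polycomb repressor" %in% states)
  ## cohesin anchors carry both peak tracks
  expect_equal(length(ctcfPeaks(ann)), 2)
  expect_equal(length(cohesinPeaks(ann)), 2)
  ## shared anchors with conflicting classes warn
  dots2 <- rbind(dots[1:2, ],
                 data.frame(anchor1 = 2e5, anchor2 = 8e5,
                            amplitude = 2, sigma = 1.5, class = "PP"))
  sim2 <- simulateContactMap(simConfig(2e6, 2e3, dots = dots2),
                             seed = 1)
  expect_warning(simulateAnnotations(sim2$truth), "conflicting")
})

test_that("kineticParams validates occupancies and rates", {
  expect_error(kineticParams(fractions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(kineticParams(D = c(5, 0.5, 0.005)), "increasing")
  expect_error(kineticParams(kOff = c(0.1, 0.2)), "equal length")
})

test_that("trajectory simulation respects the acquisition model", {
  kp <- kineticParams()
  ts <- simulateTrajectories(kp, n = 500, seed = 3)
  d <- trackTable(ts)
  expect_equal(length(ts), 500)
  expect_equal(frameInterval(ts), 0.0075)
  ## frames are consecutive from 1 within each trajectory
  expect_true(all(unlist(tapply(d$frame, d$trajectory_id,
                                function(f) all(diff(f) == 1)))))
  ## determinism
  ts2 <- simulateTrajectories(kp, n = 500, seed = 3)
  expect_identical(trackTable(ts2), d)
  ## bound molecules take much smaller jumps than fast ones
  st <- attr(ts, "trueState")
  j <- computeJumpLengths(ts)
  mj <- tapply(j$jump_um^2, st[j$trajectory_id], mean)
  expect_lt(mj[["1"]], mj[["3"]] / 20)
})

test_that("defocalization shortens fast-state trajectories", {
  kp <- kineticParams(kBleach = 0)
  ts <- simulateTrajectories(kp, n = 2000, seed = 5, maxFrames = 50)
  d <- trackTable(ts)
  st <- attr(ts, "trueState")
  len <- tapply(d$frame, d$trajectory_id, max)
  mlen <- tapply(len, st[as.integer(names(len))], mean)
  expect_gt(mlen[["1"]], mlen[["3"]] * 3)
})

test_that("FRAP simulation matches its closed form", {
  kp <- kineticParams()  # kOff = 1/13
  fr <- simulateFrap(kp, noiseSd = 0)
  expect_equal(nrow(fr), 240)
  expect_equal(attr(fr, "bleachFrame"), 20)
  expect_equal(fr$intensity[1:20], rep(1, 20))
  tPost <- fr$t_s[21:240] - fr$t_s[20]
  expect_equal(fr$intensity[21:240],
               1 - 0.3 * exp(-tPost / 13), tolerance = 1e-12)
  ## one recovery time after the bleach the dip has closed by 1 - 1/e
  i13 <- which.min(abs(tPost - 13)) + 20
  expect_equal(fr$intensity[i13], 1 - 0.3 * exp(-1), tolerance = 1e-3)
})

test_that("binding durations follow the apparent-rate contract", {
  kp <- kineticParams(kOff = 0.1, kBleach = 0.05, frameInterval = 0.1)
  d <- simulateBindingDurations(kp, exposures = c(0.1, 0.2),
                                nPer = 20000, seed = 2)
  expect_equal(unique(d$exposure_s), c(0.1, 0.2))
  expect_equal(d$duration_s, d$frames * d$exposure_s)
  ## discretized mean duration: frames = floor(t/ex) + 1 with t
  ## exponential(k_app) gives E[frames] * ex = ex / (1 - exp(-k ex))
  for (ex in c(0.1, 0.2)) {
    kApp <- 0.1 + 0.05 * ex / 0.1
    m <- mean(d$frames[d$exposure_s == ex]) * ex
    expect_equal(m, ex / (1 - exp(-kApp * ex)), tolerance = 0.03)
  }
})

test_that("expression links promoter anchors to loop amplitude", {
  dots <- rbind(
    data.frame(anchor1 = seq(1e5, 5e5, by = 1e5),
               anchor2 = seq(1e5, 5e5, by = 1e5) + 1.5e5,
               amplitude = c(2, 3, 4, 5, 6), sigma = 1.5,
               class = "EP"),
    data.frame(anchor1 = 8e5, anchor2 = 9.5e5, amplitude = 3,
               sigma = 1.5, class = "PP"),
    data.frame(anchor1 = 1.2e6, anchor2 = 1.4e6, amplitude = 3,
               sigma = 1.5, class = "cohesin"))
  sim <- simulateContactMap(simConfig(2e6, 2e3, dots = dots), seed = 1)
  g <- simulateExpression(sim$truth, linkSlope = 1, noiseSd = 0)
  ## 5 EP promoters + 2 PP promoters, none for cohesin
  expect_equal(nrow(g), 7)
  expect_equal(log(g$tpm), log(10) + log(g$amplitude),
               tolerance = 1e-12)
  ## empty-promoter truth warns and returns an empty table
  simC <- simulateContactMap(
    simConfig(2e6, 2e3, dots = dots[7, , drop = FALSE]), seed = 1)
  expect_warning(g0 <- simulateExpression(simC$truth), "no promoter")
  expect_equal(nrow(g0), 0)
})
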