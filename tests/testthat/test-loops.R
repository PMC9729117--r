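test_that("loop scores match independent window arithmetic", {
  dots <- data.frame(anchor1 = 5e5 + 1e3, anchor2 = 7e5 + 1e3,
                     amplitude = 3, sigma = 1.5, class = "EP")
  cfg <- simConfig(2e6, 2e3, dots = dots, depth = 2e7)
  sim <- simulateContactMap(cfg, seed = 2)
  ## noiseless oracle: O/E of the expected matrix, scored by a direct
  ## reimplementation of the centre/corner arithmetic
  E <- sim$expected
  d <- abs(row(E) - col(E))
  mu <- vapply(0:(nrow(E) - 1), function(k) mean(E[d == k]), 1)
  oeE <- E / mu[d + 1]
  i <- 251; j <- 351  # anchor bins (1-based) of the planted dot
  oracle <- scoreOracle(oeE, i, j, 5)
  mE <- BinnedContactMatrix(oeE, binSize = 2e3,
                            weights = rep(1, nrow(E)),
                            normalization = "oe")
  expect_equal(scoreLoops(mE, sim$truth$loops), oracle,
               tolerance = 1e-12)
  ## the noisy-map score agrees with the noiseless oracle within 10%
  oe <- toOE(sim)
  expect_equal(scoreLoops(oe, sim$truth$loops), oracle,
               tolerance = 0.1)
})

test_that("clipped or near-diagonal loop windows are undefined", {
  sim <- plainMap(chromLength = 1e6, binSize = 1e4, depth = 2e6)
  oe <- toOE(sim)
  mk <- function(b1, b2)
    LoopSet(GRanges("chrS", IRanges((b1 - 1) * 1e4 + 1, width = 1e4)),
            GRanges("chrS", IRanges((b2 - 1) * 1e4 + 1, width = 1e4)))
  expect_true(is.na(scoreLoops(oe, mk(3, 50))))   # clipped at edge
  expect_true(is.na(scoreLoops(oe, mk(40, 52))))  # reaches diagonal
  expect_false(is.na(scoreLoops(oe, mk(40, 53)))) # minimal distance
  expect_error(apa(oe, mk(3, 50)), "zero valid")
})

test_that("APA separates planted dots from random pairs", {
  dots <- rbind(dotBlock(20, "cohesin", 1e5, 3e4),
                dotBlock(10, "EP", 1.0e6, 3e4, seed = 43),
                dotBlock(20, "PP", 1.55e6, 2e4, seed = 44))
  cfg <- simConfig(2.4e6, 2e3, dots = dots, depth = 1e8)
  sim <- simulateContactMap(cfg, seed = 3)
  oe <- toOE(sim)
  ap <- apa(oe, sim$truth$loops)
  expect_gt(ap$centerRatio, 2)
  expect_equal(ap$n, 50)
  expect_equal(dim(ap$apa), c(11, 11))
  set.seed(9)
  i0 <- sample(100:1000, 100)
  rnd <- LoopSet(GRanges("chrS", IRanges((i0 - 1) * 2e3 + 1,
                                         width = 2e3)),
                 GRanges("chrS", IRanges((i0 + 99) * 2e3 + 1,
                                         width = 2e3)))
  expect_equal(apa(oe, rnd)$centerRatio, 1, tolerance = 0.1)
})

test_that("clean planted annotations classify perfectly", {
  dots <- rbind(dotBlock(10, "cohesin", 1e5, 3e4),
                dotBlock(10, "EP", 8e5, 3e4, seed = 43),
                dotBlock(5, "PP", 1.5e6, 3e4, seed = 44),
                dotBlock(5, "polycomb", 1.9e6, 3e4, seed = 45))
  sim <- simulateContactMap(simConfig(2.4e6, 2e3, dots = dots),
                            seed = 1)
  ann <- simulateAnnotations(sim$truth)
  cl <- classifyLoops(sim$truth$loops, ann)
  expect_equal(loopClass(cl), loopClass(sim$truth$loops))
  ## empty annotations: everything is "other", with a warning
  empty <- ChromatinStateTrack(GRanges())
  expect_warning(cl0 <- classifyLoops(sim$truth$loops, empty),
                 "empty annotation")
  expect_true(all(loopClass(cl0) == "other"))
})

test_that("anchor labels respect precedence and peak requirements", {
  a1 <- GRanges("chrS", IRanges(1000, 1999))
  a2 <- GRanges("chrS", IRanges(9000, 9999))
  loops <- LoopSet(a1, a2)
  seg <- GRanges("chrS", IRanges(c(1000, 1000, 9000),
                                 c(1999, 1999, 9999)))
  mcols(seg)$state <- c("active promoter", "CTCF/insulator",
                        "strong enhancer")
  peaks <- c(a1, a2)
  st <- ChromatinStateTrack(seg, ctcfPeaks = peaks,
                            cohesinPeaks = peaks)
  ## anchor 1 is P + C; P wins, so the pair is EP, not cohesin
  expect_equal(loopClass(classifyLoops(loops, st)), "EP")
  ## CTCF state without both peak tracks never labels C
  segC <- GRanges("chrS", IRanges(c(1000, 9000), c(1999, 9999)))
  mcols(segC)$state <- "CTCF/insulator"
  stNoPeak <- ChromatinStateTrack(segC, ctcfPeaks = peaks)
  expect_equal(loopClass(classifyLoops(loops, stNoPeak)), "other")
  stPeaks <- ChromatinStateTrack(segC, ctcfPeaks = peaks,
                                 cohesinPeaks = peaks)
  expect_equal(loopClass(classifyLoops(loops, stPeaks)), "cohesin")
})

test_that("differential calls recover a cohesin-specific depletion", {
  dots <- rbind(dotBlock(20, "cohesin", 1e5, 3e4),
                dotBlock(10, "EP", 1.0e6, 3e4, seed = 43),
                dotBlock(20, "PP", 1.55e6, 2e4, seed = 44))
  cc <- dots$class == "cohesin"
  dotsI <- dots
  dotsI$amplitude[cc] <- 1 + (dots$amplitude[cc] - 1) * 0.3
  simU <- simulateContactMap(
    simConfig(2.4e6, 2e3, dots = dots, depth = 1e8), seed = 1)
  simI <- simulateContactMap(
    simConfig(2.4e6, 2e3, dots = dotsI, depth = 1e8), seed = 101)
  sU <- scoreLoops(toOE(simU), simU$truth$loops)
  sI <- scoreLoops(toOE(simI), simU$truth$loops)
  dl <- differentialLoops(sU, sI)
  cls <- loopClass(simU$truth$loops)[dl$calls$loop]
  expect_gte(mean(dl$calls$call[cls == "cohesin"] == "down"), 0.9)
  expect_gte(mean(dl$calls$call[cls != "cohesin"] == "unchanged"),
             0.9)
  expect_equal(sum(dl$fractions), 1)
  expect_lt(abs(dl$meanUnchangedChange), 0.1)
})

test_that("median-centring absorbs uniform scaling", {
  set.seed(6)
  s <- rlnorm(100, 1, 0.3)
  raw <- differentialLoops(s, s * 2, medianCenter = FALSE)
  expect_true(all(raw$calls$call == "up"))
  cen <- differentialLoops(s, s * 2, medianCenter = TRUE)
  expect_true(all(cen$calls$call == "unchanged"))
  expect_error(differentialLoops(s, s[-1]), "matched")
  expect_error(differentialLoops(NA_real_, NA_real_), "no loops")
})

test_that("boundary crossing honours the anchor exclusion zone", {
  m1 <- c(1e5, 4e5, 2e5 - 800)
  m2 <- c(3e5, 5e5, 3e5)
  loops <- LoopSet(GRanges("chrS", IRanges(m1 - 500, m1 + 499)),
                   GRanges("chrS", IRanges(m2 - 500, m2 + 499)))
  bx <- annotateBoundaryCrossing(loops, boundaries = 2e5)
  expect_equal(bx$crossing, c("inter", "intra", "intra"))
  expect_equal(bx$nCrossed, c(1, 0, 0))
  ## the third loop's anchor sits on the boundary
  expect_equal(bx$anchorAtBoundary, c(FALSE, FALSE, TRUE))
  ## no boundaries: everything intra
  b0 <- annotateBoundaryCrossing(loops, boundaries = numeric(0))
  expect_true(all(b0$crossing == "intra"))
})

test_that("matched score distributions give ~50% crossing retention", {
  set.seed(2)
  sI <- rlnorm(200, 0, 0.3); dI <- runif(200, 1e5, 1e6)
  sX <- rlnorm(400, 0, 0.3); dX <- runif(400, 1e5, 1e6)
  cr <- crossingRetention(sI, dI, sX, dX)
  expect_equal(cr$fraction, 0.5, tolerance = 0.1)
  expect_equal(cr$nEvaluated + cr$nExcluded, 200)
  ## no reference in band: loop excluded, not failed
  cr2 <- crossingRetention(1, 5e5, 1, 1e5, band = 0.1)
  expect_equal(cr2$nExcluded, 1)
  expect_true(is.na(cr2$fraction))
})

test_that("crossed weak boundaries show shallower insulation dips", {
  ## strong boundary at 1 Mb (gamma 0.2), weak at 2 Mb (gamma 0.6)
  ## built as two maps sharing the insulation track convention
  ti <- cbind(c(0, 1e6, 2e6), c(1e6, 2e6, 3e6))
  cfgS <- simConfig(3e6, 2e4, tadIntervals = ti,
                    boundaryInsulation = 0.2, depth = 1.2e7)
  cfgW <- simConfig(3e6, 2e4, tadIntervals = ti,
                    boundaryInsulation = 0.6, depth = 1.2e7)
  simS <- simulateContactMap(cfgS, seed = 3)
  simW <- simulateContactMap(cfgW, seed = 3)
  ## splice: strong map left of 1.5 Mb, weak map right
  ccS <- contactCounts(simS$map)
  ccW <- contactCounts(simW$map)
  cc <- ccS
  cc[76:150, 76:150] <- ccW[76:150, 76:150]
  m <- BinnedContactMatrix(cc, binSize = 2e4)
  ins <- insulationScore(balanceICE(m), 1e5)
  ## one loop crossing only the weak boundary at 2 Mb
  loops <- LoopSet(GRanges("chrS", IRanges(1.9e6 + 1, width = 2e4)),
                   GRanges("chrS", IRanges(2.1e6 + 1, width = 2e4)),
                   loopClass = "EP")
  prof <- boundaryCrossedProfile(c(1e6, 2e6), loops, ins,
                                 flankBp = 2e5)
  expect_equal(unname(prof$groupSizes), c(1L, 1L))
  mid <- which(rownames(prof$profiles) == "0")
  expect_gt(prof$profiles[mid, "crossed"],
            prof$profiles[mid, "notCrossed"])
  ## class filter that excludes the loop empties the crossed group
  expect_warning(
    boundaryCrossedProfile(c(1e6, 2e6), loops, ins,
                           classFilter = "cohesin", flankBp = 2e5),
    "empty group")
})
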