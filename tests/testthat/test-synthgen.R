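test_that("oocyte scenes encode the requested cortex/center ratio", {
  # uniform disc: downstream ratio must be exactly 1
  oo <- makeOocyteScene(radiusPx = 60, trueRatio = 1.0, noiseSd = 0, seed = 1)
  prof <- relativePeripheralIntensity(getPlane(oo$scene, role = "mito"))
  expect_equal(prof@ratio, 1.0)

  # oracle: average the raw pixels over the analytically defined masks
  oo3 <- makeOocyteScene(radiusPx = 100, trueRatio = 3.0, noiseSd = 0,
                         seed = 1)
  p <- getPlane(oo3$scene, role = "mito")
  side <- nrow(p); c0 <- (side + 1) / 2
  d2 <- outer((seq_len(side) - c0)^2, (seq_len(side) - c0)^2, `+`)
  inner <- d2 <= (0.8 * 100)^2
  annulus <- d2 <= 100^2 & !inner
  oracleRatio <- mean(p[annulus]) / mean(p[inner])
  expect_lt(abs(oracleRatio - 3.0) / 3.0, 0.05)

  # and the measurement pipeline agrees with the oracle within discretization
  meas <- relativePeripheralIntensity(p)@ratio
  expect_lt(abs(meas - 3.0) / 3.0, 0.05)

  # default ratio is the vehicle-group value
  expect_equal(makeOocyteScene(radiusPx = 30, seed = 1)$truth@trueRatio, 1.4)

  expect_error(makeOocyteScene(radiusPx = 10, trueRatio = 1), "radiusPx")
})

test_that("expansion pairs realize the requested areas within 1%", {
  ep <- makeExpansionPair(areaBeforePx = 13231, fold = 2.877, seed = 1)
  a <- ep$truth@trueAreaPx
  expect_lt(abs(a[["before"]] - 13231) / 13231, 0.01)
  expect_lt(abs(a[["after"]] - 38061) / 38061, 0.01)

  # fold 1: both areas equal within 1%
  ep1 <- makeExpansionPair(5000, fold = 1.0, seed = 2)
  a1 <- ep1$truth@trueAreaPx
  expect_lt(abs(a1[["after"]] - a1[["before"]]) / a1[["before"]], 0.01)

  # irregularity 0 gives a disc: the mask coincides with the analytic disc
  # of radius sqrt(area/pi) at the centroid (and area matches pi r^2)
  ep0 <- makeExpansionPair(8000, fold = 2, irregularity = 0, seed = 3)
  mask <- segmentCocArea(getPlane(ep0$before, channel = 1))$mask
  area <- sum(mask)
  expect_lt(abs(area - 8000) / 8000, 0.01)
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  d2 <- outer((seq_len(nrow(mask)) - cy)^2, (seq_len(ncol(mask)) - cx)^2, `+`)
  disc <- d2 <= area / pi
  expect_lt(sum(xor(mask, disc)) / area, 0.02)

  expect_error(makeExpansionPair(1e4, fold = 2, frameSide = 50), "fit")
})

test_that("nucleus fields honor class composition and placement rules", {
  nf <- makeCocNucleusScene(227, nTunelOnly = 7, nEthd1Only = 0,
                            nDouble = 10, frameSide = 512, seed = 1)
  tr <- nf$truth@nucleusTruth
  expect_equal(nrow(tr), 227)
  expect_equal(sum(tr$class == "apoptotic"), 7)
  expect_equal(sum(tr$class == "secondary"), 10)
  # 17 TUNEL-positive in total, 10 EthD1-positive
  expect_equal(sum(tr$class %in% c("apoptotic", "secondary")), 17)
  expect_equal(sum(tr$class %in% c("necrotic", "secondary")), 10)

  # all-healthy field: marker channels are pure background
  nh <- makeCocNucleusScene(20, frameSide = 256, seed = 2)
  expect_true(all(nh$truth@nucleusTruth$class == "healthy"))
  expect_equal(diff(range(getPlane(nh$scene, role = "tunel"))), 0)
  expect_equal(diff(range(getPlane(nh$scene, role = "ethd1"))), 0)

  # two overlapping spots merge into one connected component before watershed
  tw <- makeCocNucleusScene(2, frameSide = 64, minSepPx = 0, spotSigmaPx = 3,
                            centers = cbind(c(28, 37), c(32, 32)), seed = 1)
  hp <- getPlane(tw$scene, role = "hoechst")
  ncomp <- max(EBImage::bwlabel(EBImage::Image((hp > min(hp)) * 1)))
  expect_equal(ncomp, 1)
  expect_equal(nrow(tw$truth@nucleusTruth), 2)

  # infeasible packing errors out after bounded retries
  expect_error(
    makeCocNucleusScene(200, frameSide = 64, minSepPx = 20, seed = 1),
    "cannot place")
  expect_error(makeCocNucleusScene(10, nTunelOnly = 8, nDouble = 5),
               "exceed")
})

test_that("generators are bit-identical under a fixed seed", {
  a <- makeOocyteScene(radiusPx = 40, trueRatio = 2, noiseSd = 150, seed = 7)
  b <- makeOocyteScene(radiusPx = 40, trueRatio = 2, noiseSd = 150, seed = 7)
  expect_identical(scenePixels(a$scene), scenePixels(b$scene))

  n1 <- makeCocNucleusScene(30, 2, 1, 1, frameSide = 256, noiseSd = 500,
                            seed = 11)
  n2 <- makeCocNucleusScene(30, 2, 1, 1, frameSide = 256, noiseSd = 500,
                            seed = 11)
  expect_identical(scenePixels(n1$scene), scenePixels(n2$scene))
  expect_identical(n1$truth@nucleusTruth, n2$truth@nucleusTruth)

  s1 <- simulateSteroidTable(seed = 3)
  s2 <- simulateSteroidTable(seed = 3)
  expect_identical(s1, s2)
})

test_that("multinomial outcome simulation conserves group totals", {
  gc <- simulateExperimentCounts(
    list(a = c(MII = 0.84, abnormal = 0.16),
         b = c(MII = 0.5, abnormal = 0.5)),
    nPerGroup = c(90, 50), seed = 1)
  expect_equal(unname(rowSums(counts(gc))), c(90, 50))

  # degenerate probabilities concentrate all mass
  gc1 <- simulateExperimentCounts(list(a = c(x = 1, y = 0),
                                       b = c(x = 1, y = 0)),
                                  nPerGroup = 50, seed = 2)
  expect_equal(unname(counts(gc1)[, "x"]), c(50, 50))

  # long-run first-category fraction approaches its probability
  draws <- vapply(1:2000, function(s)
    counts(simulateExperimentCounts(
      list(g = c(a = 0.84, b = 0.16), h = c(a = 0.84, b = 0.16)),
      nPerGroup = 90, seed = s))[1, "a"] / 90, numeric(1))
  se <- sqrt(0.84 * 0.16 / 90) / sqrt(2000)
  expect_lt(abs(mean(draws) - 0.84), 3 * se)

  expect_error(simulateExperimentCounts(list(a = c(x = 0.6, y = 0.5)), 10),
               "sum")
  expect_error(simulateExperimentCounts(list(a = c(x = -0.1, y = 1.1)), 10),
               "egative")
})

test_that("steroid tables honor panel membership and truncation", {
  # zero SD: replicates equal the mean exactly
  s <- defaultSteroidSettings()
  s$sds[] <- 0
  tab <- simulateSteroidTable(s$means, s$sds, nReps = 3, seed = 1)
  pr <- tab[tab$analyte == "progesterone" & tab$group == "vehicle", ]
  expect_equal(pr$concentration, rep(6.40, 3))

  # zero mean + zero sd: all-zero column
  m0 <- s$means; m0["pregnenolone", ] <- 0
  s0 <- s$sds
  tab0 <- simulateSteroidTable(m0, s0, nReps = 2, seed = 1)
  expect_true(all(tab0$concentration[tab0$analyte == "pregnenolone"] == 0))

  # concentrations never negative even at high relative SD
  mh <- matrix(0.5, 1, 2,
               dimnames = list("estrone", c("vehicle", "1e-5 M")))
  sh <- matrix(2, 1, 2, dimnames = dimnames(mh))
  th <- simulateSteroidTable(mh, sh, nReps = 50, seed = 4)
  expect_true(all(th$concentration >= 0))

  bad <- matrix(1, 1, 1, dimnames = list("caffeine", "vehicle"))
  expect_error(simulateSteroidTable(bad, bad, seed = 1), "unknown analyte")
})
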