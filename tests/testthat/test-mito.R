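test_that("oocyte segmentation recovers disc geometry", {
  plane <- discPlane(221, 100)
  oo <- segmentOocyte(plane)
  expect_lt(abs(oo@diameterPx - 200), 2)
  expect_equal(unname(oo@centerXY), c(111, 111), tolerance = 0.01)

  # blank frame: nothing to segment
  expect_error(segmentOocyte(matrix(0, 64, 64)), "no oocyte")

  # a small bright speck is excluded by the largest-component rule
  speck <- discPlane(221, 80)
  speck[5:8, 5:8] <- 5000
  ooS <- segmentOocyte(speck)
  expect_false(ooS@mask[6, 6])
  expect_lt(abs(ooS@diameterPx - 160), 2)
})

test_that("equator selection picks the maximal cross-section plane", {
  # single-plane scene
  oo1 <- makeOocyteScene(radiusPx = 40, seed = 1)
  expect_equal(selectEquator(oo1$scene), 1L)

  # 11-plane spherical stack: the middle plane (6, 1-based) is the equator
  oz <- makeOocyteScene(radiusPx = 60, trueRatio = 1.4, nZ = 11, seed = 2)
  expect_equal(selectEquator(oz$scene), 6L)
  # oracle: the generated sphere has its largest analytic cross-section at
  # the central z offset, so the segmented areas must peak there too
  areas <- vapply(1:11, function(k)
    sum(segmentOocyte(getPlane(oz$scene, role = "mito", z = k))@mask),
    numeric(1))
  expect_equal(which.max(areas), 6L)

  # exact tie: two identical planes, tie broken toward the stack middle
  p <- discPlane(101, 30)
  stack <- array(c(p, p), dim = c(101, 101, 1, 2))
  sc <- new("MultiChannelScene", pixels = stack, channelRoles = "mito",
            pixelSizeUm = NA_real_)
  expect_equal(selectEquator(sc), 1L)
})

test_that("relative peripheral intensity matches its definition", {
  # uniform disc: ratio exactly 1
  plane <- discPlane(161, 70)
  prof <- relativePeripheralIntensity(plane)
  expect_equal(prof@ratio, 1.0)
  expect_equal(prof@centerFraction, 0.8)

  # zero center intensity: ratio undefined, not infinite
  ring <- discPlane(161, 70, fg = 0, bg = 0)
  c0 <- 81
  d2 <- outer((seq_len(161) - c0)^2, (seq_len(161) - c0)^2, `+`)
  ring[d2 <= 70^2 & d2 > 56^2] <- 2000
  oo <- segmentOocyte(ring)
  profR <- relativePeripheralIntensity(ring, oo)
  expect_true(is.na(profR@ratio))
  expect_gt(profR@cortexMean, 0)
})

test_that("the ratio is scale invariant, rotation stable and cortex-monotone", {
  oo <- makeOocyteScene(radiusPx = 60, trueRatio = 2.2, noiseSd = 120,
                        seed = 5)
  plane <- getPlane(oo$scene, role = "mito")
  r0 <- relativePeripheralIntensity(plane)@ratio

  # scale invariance: multiplying intensities by c > 0 leaves the ratio alone
  expect_equal(relativePeripheralIntensity(plane * 3.7)@ratio, r0)

  # rotation by 90 degrees changes the ratio by < 1%
  rot <- t(plane)[, rev(seq_len(nrow(plane)))]
  r90 <- relativePeripheralIntensity(rot)@ratio
  expect_lt(abs(r90 - r0) / r0, 0.01)

  # adding intensity only to cortex pixels strictly increases the ratio
  seg <- segmentOocyte(plane)
  rCut <- 0.8 * seg@diameterPx / 2
  d2 <- outer((seq_len(nrow(plane)) - seg@centerXY[2])^2,
              (seq_len(ncol(plane)) - seg@centerXY[1])^2, `+`)
  cortex <- seg@mask & d2 > rCut^2
  bumped <- plane + 500 * cortex
  expect_gt(relativePeripheralIntensity(bumped, seg)@ratio, r0)

  # partition: center and cortex tile the mask disjointly
  center <- seg@mask & d2 <= rCut^2
  expect_true(all(xor(center, cortex) == seg@mask))
})

test_that("stack aggregation options report a ratio for every mode", {
  oz <- makeOocyteScene(radiusPx = 50, trueRatio = 1.8, nZ = 5, seed = 8)
  eq <- mitoProfile(oz$scene, aggregate = "equator")
  av <- mitoProfile(oz$scene, aggregate = "mean")
  expect_equal(eq$plane_index, 3)
  expect_lt(abs(eq$ratio - 1.8) / 1.8, 0.05)
  expect_lt(abs(av$ratio - 1.8) / 1.8, 0.08)
})
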