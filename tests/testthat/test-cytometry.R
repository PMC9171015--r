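test_that("particle detection counts separated nuclei exactly", {
  nf <- makeCocNucleusScene(60, frameSide = 320, seed = 3)
  det <- detectParticles(getPlane(nf$scene, role = "hoechst"))
  expect_equal(nrow(det$particles), 60)

  # blank (noise-only) channel: zero particles
  blank <- matrix(quantize16(2000 + rnorm(128^2, 0, 50)), 128, 128)
  expect_equal(nrow(detectParticles(blank)$particles), 0)

  # constant (saturated) image: threshold undefined
  expect_error(detectParticles(matrix(65535, 64, 64)),
               "threshold undefined")
})

test_that("watershed splits touching nuclei that merge into one component", {
  tw <- makeCocNucleusScene(2, frameSide = 64, minSepPx = 0, spotSigmaPx = 3,
                            centers = cbind(c(28, 37), c(32, 32)), seed = 1)
  hp <- getPlane(tw$scene, role = "hoechst")
  # merged before watershed (generator truth says two nuclei)
  ncomp <- max(EBImage::bwlabel(EBImage::Image((hp > min(hp)) * 1)))
  expect_equal(ncomp, 1)
  det <- detectParticles(hp, smoothSigmaPx = 0)
  expect_equal(nrow(det$particles), 2)
})

test_that("positivity assignment follows the colocalization rule", {
  nf <- makeCocNucleusScene(227, nTunelOnly = 7, nEthd1Only = 0,
                            nDouble = 10, frameSide = 512, seed = 5)
  cyt <- cocCytometry(nf$scene, nPlanes = 1)
  tab <- cyt$nuclei
  expect_equal(nrow(tab), 227)
  expect_equal(sum(tab$class == "apoptotic"), 7)
  expect_equal(sum(tab$class == "secondary"), 10)
  expect_equal(sum(tab$class == "necrotic_only"), 0)

  # empty marker masks leave every nucleus healthy
  det <- detectParticles(getPlane(nf$scene, role = "hoechst"))
  none <- matrix(FALSE, 512, 512)
  tabH <- assignPositivity(det, none, none)
  expect_true(all(tabH$class == "healthy"))

  # overlap exactly at the threshold counts as positive (>= rule)
  lab <- matrix(0L, 8, 8); lab[3:4, 3:4] <- 1L
  det1 <- list(particles = data.frame(nucleus_id = 1L, plane_index = 1L,
                                      x = 3.5, y = 3.5, area_px = 4L,
                                      on_border = FALSE),
               labels = lab)
  half <- matrix(FALSE, 8, 8); half[3, 3:4] <- TRUE   # exactly 2/4 pixels
  tab1 <- assignPositivity(det1, half, matrix(FALSE, 8, 8),
                           overlapMin = 0.5)
  expect_true(tab1$tunel_pos)
  under <- matrix(FALSE, 8, 8); under[3, 3] <- TRUE   # 1/4 < 0.5
  tab2 <- assignPositivity(det1, under, matrix(FALSE, 8, 8),
                           overlapMin = 0.5)
  expect_false(tab2$tunel_pos)

  expect_error(assignPositivity(det1, matrix(FALSE, 4, 4),
                                matrix(FALSE, 8, 8)), "mismatch")
})

test_that("nucleus classes partition and rates follow their definitions", {
  # classification truth table
  expect_equal(classifyNuclei(c(TRUE, TRUE, FALSE, FALSE),
                              c(FALSE, TRUE, TRUE, FALSE)),
               c("apoptotic", "secondary", "necrotic_only", "healthy"))

  # worked single-plane arithmetic: 227 total, 7 apoptotic, 10 necrotic
  tab <- data.frame(class = rep(c("apoptotic", "secondary", "healthy"),
                                c(7, 10, 210)))
  rates <- cocRates(tab)
  expect_equal(rates$n_total, 227)
  expect_equal(rates$n_apoptotic, 7)
  expect_equal(rates$n_necrotic, 10)
  expect_equal(round(rates$apoptotic_rate, 4), 0.0308)
  expect_equal(round(rates$necrotic_rate, 4), 0.0441)

  # all healthy: both rates zero
  rates0 <- cocRates(data.frame(class = rep("healthy", 50)))
  expect_equal(rates0$apoptotic_rate, 0)
  expect_equal(rates0$necrotic_rate, 0)

  # pooling identical planes leaves the rates unchanged
  rates3 <- cocRates(list(tab, tab, tab))
  expect_equal(rates3$apoptotic_rate, rates$apoptotic_rate)
  expect_equal(rates3$necrotic_rate, rates$necrotic_rate)
  expect_equal(rates3$n_total, 3 * 227)

  # empty table: rates flagged undefined
  ratesNA <- cocRates(data.frame(class = character(0)))
  expect_false(ratesNA$rates_defined)
  expect_true(is.na(ratesNA$apoptotic_rate))

  # invariants on a generated field
  nf <- makeCocNucleusScene(80, 5, 3, 4, frameSide = 320, seed = 9)
  cyt <- cocCytometry(nf$scene, nPlanes = 1)
  expect_equal(sum(table(cyt$nuclei$class)), cyt$rates$n_total)
  expect_gte(cyt$rates$n_necrotic, cyt$rates$n_secondary)
  expect_true(cyt$rates$apoptotic_rate >= 0 && cyt$rates$apoptotic_rate <= 1)
})

test_that("plane selection spaces indices through the informative depth", {
  stack9 <- array(rep(discPlane(64, 10, fg = 4000, bg = 1000), 9),
                  dim = c(64, 64, 9))
  expect_equal(selectPlanes(stack9, 3), c(3L, 5L, 7L))
  stack3 <- stack9[, , 1:3]
  expect_equal(selectPlanes(stack3, 3), c(1L, 2L, 3L))
  expect_equal(selectPlanes(stack9, 1), 5L)
  expect_error(selectPlanes(stack3, 4), "shallow")

  # planes with no spot signal are excluded from the informative range
  informative <- discPlane(64, 10, fg = 4000, bg = 1000)
  flat <- matrix(1000, 64, 64)
  stackEdge <- array(c(flat, rep(informative, 7), flat),
                     dim = c(64, 64, 9))
  idx <- selectPlanes(stackEdge, 3)
  expect_true(all(idx >= 2 & idx <= 8))
})

test_that("a pure background offset does not change counts", {
  nf <- makeCocNucleusScene(40, 3, 2, 1, frameSide = 256, seed = 12)
  p <- getPlane(nf$scene, role = "hoechst")
  n0 <- nrow(detectParticles(p)$particles)
  nOff <- nrow(detectParticles(p + 5000)$particles)
  expect_equal(n0, 40)
  expect_equal(nOff, n0)
})
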