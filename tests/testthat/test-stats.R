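test_that("chi-square matches direct computation from marginals", {
  gc <- nuclearMaturationCounts()
  rep <- contingencyChiSquare(gc)

  # independent oracle: expected from marginals, sum (O-E)^2/E
  m <- counts(gc)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  oracle <- sum((m - E)^2 / E)
  expect_equal(rep@statistic, oracle)
  expect_equal(rep@df, (nrow(m) - 1) * (ncol(m) - 1))
  expect_lt(rep@pValue, 0.001)

  # identical rows: no association at all
  same <- GroupCounts(matrix(c(40, 40, 60, 60), 2,
                             dimnames = list(c("a", "b"), c("x", "y"))))
  rep0 <- contingencyChiSquare(same)
  expect_equal(rep0@statistic, 0)
  expect_equal(rep0@pValue, 1)

  # maximal association in a 2x2
  assoc <- GroupCounts(matrix(c(10, 0, 0, 10), 2,
                              dimnames = list(c("a", "b"), c("x", "y"))))
  expect_lt(contingencyChiSquare(assoc)@pValue, 0.05)

  # low expected cells are flagged (here: expected 3.3 in two cells)
  uneven <- GroupCounts(matrix(c(10, 0, 0, 5), 2,
                               dimnames = list(c("a", "b"), c("x", "y"))))
  expect_gt(nrow(contingencyChiSquare(uneven)@details$low_expected_cells), 0)
})

test_that("pooled z-tests match the hand formula and flag extremes", {
  gc <- GroupCounts(matrix(c(30, 15, 30, 45), 2,
                           dimnames = list(c("a", "b"), c("hit", "miss"))))
  ph <- posthocProportionZTests(gc, "hit")
  pPool <- 45 / 120
  zHand <- (30 / 60 - 15 / 60) /
    sqrt(pPool * (1 - pPool) * (1 / 60 + 1 / 60))
  expect_equal(ph$statistic, zHand)
  expect_equal(ph$raw_p, 2 * pnorm(-abs(zHand)))

  # identical proportions: z = 0, p = 1
  same <- GroupCounts(matrix(c(20, 20, 30, 30), 2,
                             dimnames = list(c("a", "b"), c("hit", "miss"))))
  ph0 <- posthocProportionZTests(same, "hit")
  expect_equal(ph0$statistic, 0)
  expect_equal(ph0$raw_p, 1)

  # pooled proportion 0: z undefined, Fisher fallback flagged
  zero <- GroupCounts(matrix(c(0, 0, 30, 30), 2,
                             dimnames = list(c("a", "b"), c("hit", "miss"))))
  phF <- posthocProportionZTests(zero, "hit")
  expect_equal(phF$method, "fisher-exact")
  expect_equal(phF$raw_p, 1)

  # Bonferroni family size: all pairs of 5 groups = 10 comparisons
  gc5 <- nuclearMaturationCounts()
  ph5 <- posthocProportionZTests(gc5, "MII")
  expect_equal(nrow(ph5), 10)
  expect_equal(ph5$adjusted_p, pmin(1, ph5$raw_p * 10))
  expect_true(all(ph5$adjusted_p >= ph5$raw_p))

  # vs-reference mode compares only against the reference group
  phR <- posthocProportionZTests(gc5, "MII", comparisons = "vs-reference",
                                 reference = "vehicle")
  expect_equal(nrow(phR), 4)
  expect_true(all(phR$group1 == "vehicle"))
  expect_equal(phR$adjusted_p, pmin(1, phR$raw_p * 4))
})

test_that("ANOVA + Tukey reduces to the pooled t-test for two groups", {
  set.seed(71)
  v <- c(rnorm(6, 5, 1), rnorm(6, 6, 1))
  g <- rep(c("a", "b"), each = 6)
  rep2 <- anovaTukey(v, g)
  tp <- t.test(v ~ g, var.equal = TRUE)$p.value
  expect_equal(rep2@pairwise$adjusted_p, tp, tolerance = 1e-6)
  expect_equal(rep2@pValue, tp, tolerance = 1e-6)
  # F = t^2 identity
  expect_equal(rep2@statistic,
               unname(t.test(v ~ g, var.equal = TRUE)$statistic^2),
               tolerance = 1e-6)

  # all groups the same constant: no effect, no significant pairs
  repC <- anovaTukey(rep(3.3, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(is.na(repC@pValue))
  expect_equal(nrow(repC@pairwise), 0)
})

test_that("Kruskal-Wallis H and Dunn z match the rank formulas", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  rep3 <- kruskalDunn(v, g)
  # hand computation: mean ranks 2, 5, 8; H = 12/(N(N+1)) sum n R^2 - 3(N+1)
  expect_equal(rep3@statistic, 12 / (9 * 10) * 3 * (4 + 25 + 64) - 30)
  expect_equal(rep3@statistic, 7.2)
  expect_equal(rep3@df, 2)

  # Dunn z for pair (a, c): mean rank difference over tie-free variance
  zHand <- (2 - 8) / sqrt((9 * 10 / 12) * (1 / 3 + 1 / 3))
  zAC <- rep3@pairwise$statistic[rep3@pairwise$group1 == "a" &
                                 rep3@pairwise$group2 == "c"]
  expect_equal(zAC, zHand)
  expect_equal(rep3@pairwise$adjusted_p, pmin(1, rep3@pairwise$raw_p * 3))

  # identical groups: H = 0, p = 1
  repT <- kruskalDunn(rep(2, 9), g)
  expect_equal(repT@statistic, 0)
  expect_equal(repT@pValue, 1)

  # invariance under monotone transform of the values
  v2 <- exp(v)
  expect_equal(kruskalDunn(v2, g)@statistic, rep3@statistic)

  # invariance under group relabeling
  perm <- c(a = "c", b = "a", c = "b")[g]
  expect_equal(kruskalDunn(v, perm)@statistic, rep3@statistic)

  # tie correction agrees with stats::kruskal.test under heavy ties
  vt <- c(1, 1, 2, 2, 2, 3, 3, 4, 4, 5, 5, 5)
  gt <- rep(c("a", "b", "c"), each = 4)
  expect_equal(kruskalDunn(vt, gt)@statistic,
               unname(kruskal.test(vt, factor(gt))$statistic))
})

test_that("derived rates reproduce printed-table percentages", {
  gc <- nuclearMaturationCounts()
  rates <- deriveRates(gc, "meiotic")
  mii <- rates[rates$category == "MII", ]
  expect_equal(mii$pct[mii$group == "vehicle"], 84)
  expect_equal(mii$pct[mii$group == "1e-5 M"], 3)
  expect_equal(rates$pct_exact[rates$group == "vehicle" &
                               rates$category == "MII"], 100 * 76 / 90)

  # zero count gives 0%
  z <- GroupCounts(matrix(c(0, 5, 10, 5), 2,
                          dimnames = list(c("a", "b"), c("x", "y"))))
  rz <- deriveRates(z)
  expect_equal(rz$pct[rz$group == "a" & rz$category == "x"], 0)

  # per-group percentages sum to 100 up to integer rounding
  sums <- tapply(rates$pct, rates$group, sum)
  expect_true(all(abs(sums - 100) <= 1))
  sumsExact <- tapply(rates$pct_exact, rates$group, sum)
  expect_equal(as.numeric(sumsExact), rep(100, 5))

  # chi-square is invariant under group relabeling
  m <- counts(gc)
  shuffled <- GroupCounts(m[c(3, 1, 5, 2, 4), ])
  expect_equal(contingencyChiSquare(GroupCounts(m))@statistic,
               contingencyChiSquare(shuffled)@statistic)
})
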