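test_that("Dice handles identity, disjointness, counts and empty masks", {
  a <- array(0L, c(10, 10, 10)); a[1:5, 1:5, 1:5] <- 1L
  b <- array(0L, c(10, 10, 10)); b[6:10, 6:10, 6:10] <- 1L
  expect_equal(diceCoefficient(asBinary(a), asBinary(a)), 1.0)
  expect_equal(diceCoefficient(asBinary(a), asBinary(b)), 0.0)
  # |A| = |B| = 100, |A n B| = 79 -> 0.79
  x <- array(0L, c(10, 10, 10)); x[1:100] <- 1L
  y <- array(0L, c(10, 10, 10)); y[22:121] <- 1L
  expect_equal(diceCoefficient(asBinary(x), asBinary(y)), 0.79)
  # symmetry and brute-force agreement on random masks
  set.seed(21)
  for (i in 1:20) {
    p <- randomMask(c(8, 8, 8), 0.3); q <- randomMask(c(8, 8, 8), 0.3)
    expect_equal(diceCoefficient(asBinary(p), asBinary(q)), bfDice(p, q))
    expect_equal(diceCoefficient(asBinary(p), asBinary(q)),
                 diceCoefficient(asBinary(q), asBinary(p)))
  }
  # both empty: defined as 1 with an audit flag
  e <- asBinary(array(0L, c(4, 4, 4)))
  d <- diceCoefficient(e, e)
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "bothEmpty"))
  expect_error(diceCoefficient(asBinary(a), e), "shape")
})

test_that("HD95 equals the exhaustive surface-distance computation", {
  a <- array(0L, c(20, 20, 20)); a[5:7, 5:7, 5:7] <- 1L
  b <- array(0L, c(20, 20, 20)); b[8:10, 5:7, 5:7] <- 1L
  expect_equal(hd95(asBinary(a), asBinary(b)), 3.0)
  expect_equal(hd95(asBinary(a), asBinary(a)), 0.0)
  set.seed(22)
  for (i in 1:15) {
    p <- randomMask(c(12, 12, 12), 0.05); q <- randomMask(c(12, 12, 12), 0.05)
    if (!any(p != 0) || !any(q != 0)) next
    expect_equal(hd95(asBinary(p), asBinary(q)), bfHd95(p, q), tolerance = 1e-10)
    expect_equal(hd95(asBinary(p), asBinary(q)), hd95(asBinary(q), asBinary(p)))
  }
})

test_that("HD95 is spacing-aware, bounded by the exact Hausdorff distance", {
  set.seed(23)
  p <- randomMask(c(10, 10, 10), 0.05); q <- randomMask(c(10, 10, 10), 0.05)
  sp <- c(0.5, 1, 2)
  expect_equal(hd95(asBinary(p, sp), asBinary(q, sp)), bfHd95(p, q, sp),
               tolerance = 1e-10)
  # doubling the spacing doubles the distance
  expect_equal(hd95(asBinary(p, 2 * sp), asBinary(q, 2 * sp)),
               2 * hd95(asBinary(p, sp), asBinary(q, sp)), tolerance = 1e-10)
  # the 95th percentile never exceeds the maximum surface distance
  expect_lte(hd95(asBinary(p), asBinary(q)),
             hd95(asBinary(p), asBinary(q), percentile = 1))
  expect_error(hd95(asBinary(p), asBinary(array(0L, c(10, 10, 10)))), "empty")
})

test_that("Bland-Altman bias and limits of agreement", {
  x <- c(5.2, 6.1, 4.8, 5.9, 6.3)
  same <- blandAltman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loaLow, same$loaHigh), c(0, 0))
  # constant offset: bias is the offset, SD zero
  off <- blandAltman(x, x + 0.31)
  expect_equal(off$bias, 0.31)
  expect_equal(off$sd, 0)
  # random pairs match the direct formulas
  set.seed(24)
  a <- rnorm(50); b <- a + rnorm(50, 0.1, 0.3)
  ba <- blandAltman(a, b)
  expect_equal(ba$bias, mean(b - a))
  expect_equal(ba$loaHigh, mean(b - a) + 1.96 * sd(b - a))
  # large Gaussian samples: ~95% of differences inside the limits
  a <- rnorm(5000); b <- a + rnorm(5000)
  ba <- blandAltman(a, b)
  frac <- mean(ba$differences >= ba$loaLow & ba$differences <= ba$loaHigh)
  expect_gt(frac, 0.93); expect_lt(frac, 0.97)
  expect_error(blandAltman(1:3, 1:4), "length")
  expect_error(blandAltman(1:2, 1:2), "3 pairs")
})

test_that("Gwet AC1 reproduces the hand-computed example and its bounds", {
  rt <- data.frame(r1 = c("A", "A", "A", "B"), r2 = c("A", "A", "B", "B"))
  g <- gwetAC1(rt)
  expect_equal(g@details$pa, 0.75)
  expect_equal(g@details$pe, 0.46875)
  expect_equal(g@value, (0.75 - 0.46875) / (1 - 0.46875), tolerance = 1e-6)
  expect_true(g@ciLower <= g@value && g@value <= g@ciUpper)
  # perfect agreement over >= 2 used categories
  perf <- data.frame(r1 = c("A", "B", "A", "B"), r2 = c("A", "B", "A", "B"))
  expect_equal(gwetAC1(perf)@value, 1.0)
  # category relabeling leaves the statistic unchanged
  relab <- data.frame(r1 = chartr("AB", "XY", rt$r1),
                      r2 = chartr("AB", "XY", rt$r2))
  expect_equal(gwetAC1(relab)@value, g@value)
})

test_that("Gwet AC1 tends to zero for independent uniform ratings", {
  set.seed(25)
  n <- 10000L
  rt <- data.frame(r1 = sample(c("a", "b", "c"), n, TRUE),
                   r2 = sample(c("a", "b", "c"), n, TRUE))
  g <- gwetAC1(rt)
  expect_lt(abs(g@value), 0.05)
  expect_identical(g@n, n)
})

test_that("Gwet AC1 uses pairwise-complete subjects and validates inputs", {
  rt <- data.frame(r1 = c("A", "A", NA, "B", "A"),
                   r2 = c("A", NA, "B", "B", "A"))
  g <- gwetAC1(rt)
  expect_identical(g@n, 3L)       # subjects 1, 4, 5
  expect_error(gwetAC1(data.frame(r1 = c("A", "A"), r2 = c(NA, NA))),
               "no usable ratings")
  expect_error(gwetAC1(data.frame(r1 = "A", r2 = "A")), "at least 2")
  expect_error(gwetAC1(data.frame(r1 = c("A", "A"), r2 = c("A", "A"))),
               "one category")
  # fixing the category set resolves the single-observed-category case
  gFix <- gwetAC1(data.frame(r1 = c("A", "A"), r2 = c("A", "A")),
                  categories = c("A", "B"))
  expect_equal(gFix@value, 1.0)
})

test_that("per-class mask comparison reports Dice and HD95 together", {
  ph <- smallPhantom()
  tab <- compareMasks(ph$labels, ph$labels)
  expect_identical(tab$class, c("brain", "skull", "subcutaneous_fat", "muscle"))
  expect_true(all(tab$dice == 1))
  expect_true(all(tab$hd95_mm == 0))
})
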