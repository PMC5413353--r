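test_that("Freedman-Diaconis selection matches hand-computed cases", {
  # IQR = 10 at n = 1000: width 10/1000^(1/3) = 1, K = 90 on [0, 90]
  v <- rep(c(0, 10), 500)
  sel <- selectBins(v, 0, 90)
  expect_equal(nBins(sel), 90L)
  expect_equal(sel@binWidth, 1, tolerance = 1e-12)

  # IQR = 45 at n = 8: width 22.5, K = ceil(90 / 22.5) = 4
  v <- c(0, 0, 0, 0, 45, 45, 45, 45)
  sel <- selectBins(v, 0, 90)
  expect_equal(nBins(sel), 4L)
  expect_equal(sel@binWidth, 22.5)
})

test_that("doubling the spread doubles the width and halves the bins", {
  set.seed(21)
  v <- runif(500, 0, 20)
  s1 <- selectBins(v, 0, 90)
  s2 <- selectBins(v * 2, 0, 90)
  expect_equal(s2@binWidth, 2 * s1@binWidth, tolerance = 1e-12)
  expect_equal(nBins(s2), as.integer(ceiling(90 / s2@binWidth)))
  expect_lte(nBins(s2), as.integer(ceiling(nBins(s1) / 2)) + 1L)
})

test_that("bin selection clamps to [3, 100] and rejects zero IQR", {
  # microscopic IQR would explode K; clamp at 100
  v <- c(rep(0.0001, 500), rep(0.0002, 500))
  expect_equal(nBins(selectBins(v, 0, 90)), 100L)
  # huge IQR at tiny n floors at 3
  expect_equal(nBins(selectBins(c(0, 1, 89, 90), 0, 90)), 3L)
  expect_error(selectBins(rep(5, 50), 0, 90), "interquartile")
  expect_error(selectBins(c(1, 2, 3), 0, 90), "at least 4")
})

test_that("the permutation test is seed-deterministic", {
  a <- simulateCoorientation(orientationSimConfig(
    n = 600, seed = 1, sigmaX = 25, alpha = 0.1))
  b <- simulateCoorientation(orientationSimConfig(
    n = 600, seed = 2, sigmaX = 25, alpha = 0.3))
  r1 <- permutationTest(a, b, k = 15, nIter = 30, seed = 5)
  r2 <- permutationTest(a, b, k = 15, nIter = 30, seed = 5)
  expect_identical(r1@pValue, r2@pValue)
  expect_identical(r1@fractionContradicting, r2@fractionContradicting)
  expect_true(validObject(r1))
})

test_that("identical conditions contradict about half the time", {
  a <- simulateCoorientation(orientationSimConfig(
    n = 1500, seed = 3, sigmaX = 25, alpha = 0.2))
  r <- permutationTest(a, a, k = 15, nIter = 100, seed = 7)
  expect_gt(r@fractionContradicting, 0.3)
  expect_lt(r@fractionContradicting, 0.7)
})

test_that("well-separated conditions report the floored p-value", {
  a <- simulateCoorientation(orientationSimConfig(
    n = 2000, seed = 4, sigmaX = 25, alpha = 0))
  b <- simulateCoorientation(orientationSimConfig(
    n = 2000, seed = 5, sigmaX = 25, alpha = 0.5))
  r <- permutationTest(a, b, k = 15, statistic = "LI", nIter = 100,
                       seed = 8)
  expect_equal(r@fractionContradicting, 0)
  expect_equal(r@pValue, 0.01)   # floor 1/nIter, never 0
  expect_equal(r@direction, "a_less")
  expect_lt(r@statisticA, r@statisticB)
})

test_that("the permutation test rejects degenerate inputs", {
  a <- PairedSample(runif(4, -90, 90), runif(4, -90, 90))
  expect_error(permutationTest(a, a, k = 5, subsampleFraction = 0.25,
                               seed = 1),
               "subsample")
  b <- PairedSample(runif(40, 0, 10), runif(40, 0, 10),
                    mode = "colocalization")
  big <- PairedSample(runif(40, -90, 90), runif(40, -90, 90))
  expect_error(permutationTest(big, b, k = 5, seed = 1), "mode")
})

test_that("condition sets compute per-sample indices with one shared K", {
  samples <- lapply(1:3, function(s) simulateCoorientation(
    orientationSimConfig(n = 400, seed = s, sigmaX = 25, alpha = 0.3)))
  cs <- conditionSet("treated", samples, k = 15)
  idx <- conditionIndices(cs, seed = 1)
  expect_equal(nrow(idx), 3L)
  expect_named(idx, c("condition", "label", "n", "gi", "li"))
  expect_true(all(idx$n == 400))

  ctrl <- conditionSet("control", lapply(4:6, function(s)
    simulateCoorientation(orientationSimConfig(
      n = 400, seed = s, sigmaX = 25, alpha = 0))), k = 15)
  cmp <- compareConditions(cs, ctrl, statistic = "LI", seed = 2)
  expect_s3_class(cmp$test, "htest")
  expect_equal(nrow(cmp$indicesB), 3L)

  badK <- conditionSet("control", ctrl@samples, k = 10)
  expect_error(compareConditions(cs, badK), "different K")
  mixed <- list(samples[[1]],
                PairedSample(runif(10), runif(10), mode = "colocalization"))
  expect_error(conditionSet("mixed", mixed, k = 15), "mode")
})
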