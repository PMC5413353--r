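test_that("truncated normal draws respect bounds and closed-form moments", {
  v <- sampleTruncatedNormal(5000, 0, 40, -90, 90, seed = 1)
  expect_true(all(v > -90 & v < 90))
  expect_length(v, 5000)

  # degenerate spread collapses onto the mean
  v <- sampleTruncatedNormal(1000, 10, 1e-6, -90, 90, seed = 2)
  expect_equal(mean(v), 10, tolerance = 1e-4)

  # empirical sd matches the analytic truncated-normal sd within 2%
  v <- sampleTruncatedNormal(1e5, 0, 17, -90, 90, seed = 3)
  expect_equal(sd(v), truncNormSd(0, 17, -90, 90), tolerance = 0.02)
  # heavier truncation, off-centre mean
  v <- sampleTruncatedNormal(1e5, 30, 60, -90, 90, seed = 4)
  expect_equal(sd(v), truncNormSd(30, 60, -90, 90), tolerance = 0.02)
  expect_error(sampleTruncatedNormal(10, 0, -1, 0, 1), "sigma")
})

test_that("co-orientation output is conserved, bounded and reproducible", {
  cfg <- orientationSimConfig(n = 1234, seed = 5, sigmaX = 30, alpha = 0.4)
  s1 <- simulateCoorientation(cfg)
  expect_equal(sampleSize(s1), 1234L)
  expect_true(all(abs(xValues(s1)) <= 90), all(abs(yValues(s1)) <= 90))
  s2 <- simulateCoorientation(cfg)
  expect_identical(xValues(s1), xValues(s2))
  expect_identical(yValues(s1), yValues(s2))
  s3 <- simulateCoorientation(orientationSimConfig(
    n = 1234, seed = 6, sigmaX = 30, alpha = 0.4))
  expect_false(identical(xValues(s1), xValues(s3)))
})

test_that("proportional interaction scales the alignment by 1 - alpha", {
  base <- simulateCoorientation(orientationSimConfig(
    n = 2000, seed = 7, sigmaX = 35, alpha = 0))
  thetaPre <- alignmentValues(base)
  for (a in c(0.3, 0.7, 1)) {
    s <- simulateCoorientation(orientationSimConfig(
      n = 2000, seed = 7, sigmaX = 35, alpha = a))
    expect_equal(alignmentValues(s), (1 - a) * thetaPre, tolerance = 1e-9)
  }
  # alpha = 0 leaves the draws untouched
  again <- simulateCoorientation(orientationSimConfig(
    n = 2000, seed = 7, sigmaX = 35, alpha = 0))
  expect_identical(xValues(again), xValues(base))
  expect_error(orientationSimConfig(n = 10, seed = 1, sigmaX = 10,
                                    alpha = 1.5),
               "alpha")
})

test_that("constant-zeta interaction shifts by min(zeta, gap)", {
  pre <- simulateCoorientation(orientationSimConfig(
    n = 2000, seed = 8, sigmaX = 25, interaction = "constant", zeta = 0))
  thetaPre <- alignmentValues(pre)
  post <- simulateCoorientation(orientationSimConfig(
    n = 2000, seed = 8, sigmaX = 25, interaction = "constant", zeta = 10))
  expect_equal(alignmentValues(post), pmax(thetaPre - 10, 0),
               tolerance = 1e-9)
})

test_that("negative alpha moves pairs apart without leaving the domain", {
  pre <- simulateCoorientation(orientationSimConfig(
    n = 2000, seed = 9, sigmaX = 25, alpha = 0))
  post <- simulateCoorientation(orientationSimConfig(
    n = 2000, seed = 9, sigmaX = 25, alpha = -0.5))
  expect_true(all(abs(xValues(post)) <= 90))
  expect_true(all(abs(yValues(post)) <= 90))
  expect_gt(meanAlignment(post), meanAlignment(pre))
})

test_that("co-localization generator honours its degenerate limits", {
  s <- simulateColocalization(colocSimConfig(
    n = 800, seed = 10, sigmaZeta = 0, muZeta = 1))
  expect_identical(xValues(s), yValues(s))   # perfect 1:1 interaction
  expect_true(all(xValues(s) >= 0 & xValues(s) <= 1))

  s <- simulateColocalization(colocSimConfig(
    n = 5000, seed = 11, sigmaZeta = 0.2, interactingFraction = 0))
  expect_true(all(yValues(s) >= 0 & yValues(s) <= 1))
  expect_lt(abs(cor(xValues(s), yValues(s))), 0.05)  # independent subgroups

  s2 <- simulateColocalization(colocSimConfig(
    n = 5000, seed = 11, sigmaZeta = 0.2, interactingFraction = 0))
  expect_identical(yValues(s), yValues(s2))
})

test_that("weaker multiplicative coupling lowers the local index", {
  li <- vapply(c(0.05, 0.1, 0.2, 0.4), function(sz)
    mean(vapply(1:3, function(s)
      localIndex(computeDeBias(simulateColocalization(colocSimConfig(
        n = 3000, seed = s, sigmaZeta = sz)), k = 19, seed = s)),
      numeric(1))),
    numeric(1))
  expect_true(all(diff(li) < 0))
})

test_that("configs validate their parameter ranges", {
  expect_error(colocSimConfig(n = 10, seed = 1, muX = 1.5), "muX")
  expect_error(colocSimConfig(n = 10, seed = 1, interactingFraction = 2),
               "interactingFraction")
  expect_error(orientationSimConfig(n = 0, seed = 1, sigmaX = 10), "n")
  expect_output(show(orientationSimConfig(n = 10, seed = 1, sigmaX = 10)),
                "proportional")
})
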