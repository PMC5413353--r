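test_that("alignment angle implements the folded axial difference", {
  expect_equal(alignmentAngle(30, 50), 20)
  expect_equal(alignmentAngle(77, 77), 0)
  expect_equal(alignmentAngle(-80, 80), 20)   # through the axial wrap
  expect_equal(alignmentAngle(-90, 90), 0)    # same axis
  expect_equal(alignmentAngle(45, -45), 90)   # maximal misalignment
  # inputs are wrapped mod 180 first
  expect_equal(alignmentAngle(135, -45), 0)
  expect_error(alignmentAngle(NaN, 0), "finite")
})

test_that("orientation samples wrap inputs into [-90, 90]", {
  ps <- PairedSample(c(135, 10), c(20, 170), mode = "orientation")
  expect_equal(xValues(ps), c(-45, 10))
  expect_equal(yValues(ps), c(20, -10))
  expect_equal(wrapOrientation(90), 90)
  expect_error(PairedSample(1:3, 1:2), "length")
  expect_error(PairedSample(-1, 1, mode = "colocalization"),
               "non-negative")
})

test_that("percentile normalization maps p5/p95 to 0/1 and clips", {
  v <- 0:100
  nv <- normalizeChannel(v)
  expect_equal(nv[v == 5], 0)     # p5 of 0..100 is 5
  expect_equal(nv[v == 95], 1)
  expect_equal(nv[v == 50], 0.5)
  expect_equal(nv[v == 100], 1)   # clipped above p95
  expect_equal(nv[v == 0], 0)     # clipped below p5
  expect_true(all(nv >= 0 & nv <= 1))
  expect_error(normalizeChannel(rep(3, 100)), "percentile")
})

test_that("intensity differences live on [-1, 1] and vanish for x == y", {
  x <- runif(200, 10, 1000)
  ps <- PairedSample(x, x, mode = "colocalization")
  expect_equal(intensityDifference(ps), rep(0, 200))
  ps2 <- PairedSample(x, rev(x), mode = "colocalization")
  d <- intensityDifference(ps2)
  expect_true(all(d >= -1 & d <= 1))
  expect_error(intensityDifference(PairedSample(1, 2)), "colocalization")
})

test_that("resampling is seed-reproducible and degenerate for constants", {
  ps <- PairedSample(rep(33, 40), rep(33, 40))
  expect_equal(resampledAlignment(ps, seed = 5), rep(0, 40))

  cfg <- orientationSimConfig(n = 500, seed = 2, sigmaX = 25, alpha = 0.3)
  s <- simulateCoorientation(cfg)
  r1 <- resampledAlignment(s, seed = 99)
  r2 <- resampledAlignment(s, seed = 99)
  expect_identical(r1, r2)
  expect_false(identical(r1, resampledAlignment(s, seed = 100)))
})

test_that("seeded operations leave the caller's RNG stream untouched", {
  set.seed(123)
  expected <- runif(5)
  set.seed(123)
  ps <- PairedSample(seq(-80, 80, length.out = 50),
                     seq(80, -80, length.out = 50))
  invisible(simulateCoorientation(
    orientationSimConfig(n = 100, seed = 9, sigmaX = 20)))
  invisible(computeDeBias(ps, k = 10, seed = 4))
  invisible(sampleTruncatedNormal(20, 0, 10, -90, 90, seed = 2))
  expect_identical(runif(5), expected)
})

test_that("GI + LI equals EMD(uniform, observed) by construction", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    ps <- PairedSample(runif(n, -90, 90), runif(n, -90, 90))
    r <- computeDeBias(ps, k = sample(2:30, 1), seed = i)
    expect_equal(globalIndex(r) + localIndex(r), r@emdObserved,
                 tolerance = 1e-12)
    expect_equal(globalIndex(r), r@emdResampled, tolerance = 1e-12)
  }
  # colocalization mode too
  ps <- PairedSample(runif(300, 0, 500), runif(300, 0, 500),
                     mode = "colocalization")
  r <- computeDeBias(ps, k = 19, seed = 1)
  expect_equal(globalIndex(r) + localIndex(r), r@emdObserved,
               tolerance = 1e-12)
})

test_that("constant identical inputs give the maximal GI and zero LI", {
  for (k in 2:50) {
    r <- computeDeBias(PairedSample(rep(12, 30), rep(12, 30)),
                       k = k, seed = 1)
    expect_equal(globalIndex(r), (k - 1) / 2, tolerance = 1e-12)
    expect_identical(localIndex(r), 0)
  }
})

test_that("perfect pairwise alignment with uniform marginals maximises LI", {
  set.seed(8)
  x <- runif(1e5, -90, 90)
  r <- computeDeBias(PairedSample(x, x), k = 15, seed = 8)
  expect_lt(abs(localIndex(r) - 7), 0.2)
  expect_lt(globalIndex(r), 0.2)
})

test_that("averaging several resampled histograms is deterministic", {
  cfg <- orientationSimConfig(n = 400, seed = 3, sigmaX = 30, alpha = 0.2)
  s <- simulateCoorientation(cfg)
  r1 <- computeDeBias(s, k = 15, seed = 7, resampleReps = 5)
  r2 <- computeDeBias(s, k = 15, seed = 7, resampleReps = 5)
  expect_identical(globalIndex(r1), globalIndex(r2))
  expect_equal(r1@resampleReps, 5L)
  expect_equal(sum(frequencies(r1@resampled)), 1, tolerance = 1e-12)
  expect_equal(globalIndex(r1) + localIndex(r1), r1@emdObserved,
               tolerance = 1e-12)
})

test_that("anti-alignment produces negative local indices", {
  li <- vapply(1:10, function(s)
    localIndex(simDebias(sigma = 25, alpha = -0.3, n = 3000, seed = s)),
    numeric(1))
  expect_lt(mean(li), 0)
})

test_that("GI decreases monotonically with the marginal spread", {
  sigmas <- c(5, 10, 20, 40, 80)
  gi <- vapply(sigmas, function(sg)
    mean(vapply(1:20, function(s)
      globalIndex(simDebias(sigma = sg, alpha = 0, n = 2000, seed = s)),
      numeric(1))),
    numeric(1))
  expect_true(all(diff(gi) < 0))
})

test_that("LI is a lower bound for the true local contribution", {
  # constant-zeta interactions; compare against the pre-interaction
  # observed alignment obtained from the same base draws (zeta = 0)
  slack <- vapply(1:20, function(s) {
    pre <- simulateCoorientation(orientationSimConfig(
      n = 3000, seed = s, sigmaX = 25, interaction = "constant", zeta = 0))
    post <- simulateCoorientation(orientationSimConfig(
      n = 3000, seed = s, sigmaX = 25, interaction = "constant", zeta = 10))
    u <- uniformReference(15)
    emdPre <- emd(u, quantize(alignmentValues(pre), 0, 90, 15))
    r <- computeDeBias(post, k = 15, seed = s)
    localIndex(r) - (r@emdObserved - emdPre)
  }, numeric(1))
  expect_lt(mean(slack), 0.2)
})

test_that("reducing normalized intensity differences increases LI", {
  cfg <- colocSimConfig(n = 3000, seed = 4, sigmaZeta = 0.3)
  s <- simulateColocalization(cfg)
  shrunk <- PairedSample(xValues(s),
                         yValues(s) + 0.7 * (xValues(s) - yValues(s)),
                         mode = "colocalization")
  liFull <- localIndex(computeDeBias(s, k = 19, seed = 4))
  liShrunk <- localIndex(computeDeBias(shrunk, k = 19, seed = 4))
  expect_gt(liShrunk, liFull)
})

test_that("results print and validate", {
  r <- simDebias(sigma = 20, alpha = 0.2, n = 500, seed = 1)
  expect_output(show(r), "global index")
  expect_true(validObject(r))
  expect_equal(sampleMode(r), "orientation")
  expect_equal(sampleSize(r), 500L)
  expect_equal(nBins(r), 15L)
})
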