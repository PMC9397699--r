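test_that("a perfectly linear divergence curve recovers its slope exactly", {
  curve <- new("DivergenceCurve", steps = 0:10,
               meanLogDist = 0.5 * (0:10), meanDist = exp(0.5 * (0:10)),
               nPairs = rep(50L, 11), dt = 1, extent = 1e9)
  res <- largestLyapunov(curve, fitRange = c(0, 10))
  expect_equal(lleValue(res), 0.5)
  expect_equal(res@r2, 1)
})

test_that("divergence-curve estimate matches the Jacobian oracle for maps", {
  xl <- logisticSeries()
  est <- largestLyapunov(divergenceCurve(delayEmbed(xl, 1, 2), theiler = 1,
                                         maxSteps = 20, dt = 1))
  expect_equal(lleValue(est), log(2), tolerance = 0.07 / log(2))

  xh <- henonSeries()
  oracle <- lleOracle(chaoticSystemSpec("henon"), 5e4)
  esth <- largestLyapunov(divergenceCurve(delayEmbed(xh, 1, 2), theiler = 1,
                                          maxSteps = 15, dt = 1))
  expect_equal(lleValue(esth), oracle, tolerance = 0.05 / oracle)
})

test_that("sign trichotomy: chaos positive, limit cycle zero, damped negative", {
  xl <- logisticSeries()
  expect_gt(lleValue(largestLyapunov(divergenceCurve(
    delayEmbed(xl, 1, 2), theiler = 1, maxSteps = 20))), 0.3)

  xs <- sin(2 * pi * (0:1999) / 64)
  expect_lt(abs(lleValue(largestLyapunov(divergenceCurve(
    delayEmbed(xs, 16, 2), theiler = 16, maxSteps = 30)))), 0.05)

  xd <- simulateSeries(chaoticSystemSpec("damped_oscillator",
                                         list(decay = 0.3, omega = 2 * pi,
                                              dt = 0.05), nSamples = 600))
  expect_lt(lleValue(largestLyapunov(divergenceCurve(
    delayEmbed(xd, 5, 2), theiler = 5, maxSteps = 30, dt = 0.05))), -0.1)
})

test_that("duplicated trajectories with zero separations do not poison the curve", {
  x <- rep(sin(2 * pi * (0:199) / 20), 2)   # exact duplicates, E = 0 pairs
  cv <- divergenceCurve(delayEmbed(x, 5, 2), theiler = 5, maxSteps = 10)
  expect_true(all(is.finite(cv@meanLogDist)))
  expect_true(all(cv@nPairs > 0))
})

test_that("auto fit range is stable once the curve has saturated", {
  xl <- logisticSeries()
  tr <- delayEmbed(xl, 1, 2)
  l20 <- lleValue(largestLyapunov(divergenceCurve(tr, theiler = 1, maxSteps = 20)))
  l40 <- lleValue(largestLyapunov(divergenceCurve(tr, theiler = 1, maxSteps = 40)))
  expect_equal(l20, l40, tolerance = 0.01)
})

test_that("the single-signal feature is deterministic and respects ceilings", {
  ep <- plantedEpochs()
  x <- epochData(ep)[1, 1, ]
  f1 <- lleFeature(x, embeddingParams(maxLag = 10, maxDim = 3), dt = 1 / 128)
  f2 <- lleFeature(x, embeddingParams(maxLag = 10, maxDim = 3), dt = 1 / 128)
  expect_identical(f1, f2)
  lag <- selectLag(mutualInformationCurve(x, 10, 16))
  expect_lte(lag, 10)
  expect_lte(selectDimension(x, lag, 3), 3)
})

test_that("stage errors carry the failing stage name", {
  expect_error(lleFeature(rep(1, 300), embeddingParams()),
               "mutual-information")
})

test_that("planted chaoticity difference yields a detectable feature effect", {
  ep <- plantedEpochs()   # 60 epochs/class, single channel, r 3.9 vs 3.6
  feat <- lleFeatureSets(ep, list(s = embeddingParams(maxLag = 30, maxDim = 10)))
  a <- feat[feat$label == "open", 3]
  b <- feat[feat$label == "fist", 3]
  es <- (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  expect_gt(abs(es), 0.5)
})

test_that("label-free feature sets deduplicate equal parameter sets", {
  ep <- plantedEpochs()
  sub <- chaolle:::epochSubset(ep, 1:10)
  p <- embeddingParams(maxLag = 10, maxDim = 3)
  f <- lleFeatureSets(sub, list(open = p, fist = p))
  expect_identical(f$lle_C3_open, f$lle_C3_fist)
  single <- lleFeatureSets(sub, list(s = p))
  expect_equal(f$lle_C3_open, single$lle_C3_s)
})

test_that("label-keyed feature matrix errors when too many epochs fail", {
  ep <- plantedEpochs()
  sub <- chaolle:::epochSubset(ep, 1:10)
  # ceilings impossible at this epoch length: every epoch is skipped
  bad <- embeddingParams(maxLag = 340, maxDim = 60)
  expect_error(lleFeatureMatrix(sub, bad), "failed feature extraction")
})
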