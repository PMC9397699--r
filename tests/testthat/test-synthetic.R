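test_that("logistic map simulation matches direct iteration and fixed points", {
  # r = 2.5: orbit contracts to the fixed point 1 - 1/r = 0.6
  s <- simulateSeries(chaoticSystemSpec("logistic", list(r = 2.5), 0.3, 1000))
  expect_equal(tail(s, 1), 0.6, tolerance = 1e-8)

  # r = 4: exact 10-step orbit, computed independently by Reduce
  orbit <- Reduce(function(x, i) 4 * x * (1 - x), seq_len(9),
                  accumulate = TRUE, init = 0.2)
  expect_identical(
    simulateSeries(chaoticSystemSpec("logistic", list(r = 4), 0.2, 10)),
    orbit)
})

test_that("Henon orbit stays finite and bounded on the attractor", {
  s <- simulateSeries(chaoticSystemSpec("henon", nSamples = 1e5,
                                        transientDiscard = 100))
  expect_true(all(is.finite(s)))
  expect_true(all(abs(s) <= 2))
})

test_that("spec invariants are enforced", {
  expect_error(chaoticSystemSpec("logistic", initialState = 1.5),
               "logistic initial state")
  expect_error(chaoticSystemSpec("logistic", nSamples = 10,
                                 transientDiscard = 10), "transientDiscard")
  expect_error(chaoticSystemSpec("lorenz", list(dt = -0.1)), "dt")
})

test_that("Lyapunov oracle reproduces analytic exponents", {
  expect_equal(lleOracle(chaoticSystemSpec("logistic", list(r = 4)), 1e5),
               log(2), tolerance = 0.01)
  expect_equal(lleOracle(chaoticSystemSpec("logistic", list(r = 2.5), 0.3), 1e4),
               log(0.5), tolerance = 0.01)
  # Henon reference largest exponent ~ 0.419
  expect_equal(lleOracle(chaoticSystemSpec("henon"), 5e4), 0.419,
               tolerance = 0.01)
  # limit cycle: zero; damped oscillator: -decay
  expect_lt(abs(lleOracle(chaoticSystemSpec("sine"), 1e4)), 0.05)
  expect_lt(lleOracle(chaoticSystemSpec("damped_oscillator",
                                        list(decay = 0.3, omega = 2 * pi,
                                             dt = 0.05)), 3e4), -0.2)
})

test_that("Lorenz RK4 oracle is near the reference exponent", {
  expect_equal(lleOracle(chaoticSystemSpec("lorenz"), 1e4), 0.9,
               tolerance = 0.1)
})

test_that("ERD epoch sets have the contracted shape and labels", {
  cfg <- erdConfig(nEpochsPerClass = 5, fs = 128, seed = 7)
  ep <- generateErdEpochs(cfg)
  expect_s4_class(ep, "EpochSet")
  expect_equal(dim(epochData(ep)),
               c(10, 2, round((200 + 2500) * 128 / 1000)))
  expect_equal(epochLabels(ep), rep(c("open", "fist"), each = 5))
  expect_equal(channelNames(ep), c("C3", "CP5"))
})

test_that("epoch generation is reproducible and channel-order invariant", {
  cfg <- erdConfig(nEpochsPerClass = 4, fs = 128, seed = 11)
  e1 <- generateErdEpochs(cfg)
  e2 <- generateErdEpochs(cfg)
  expect_identical(epochData(e1), epochData(e2))

  cfgRev <- erdConfig(nEpochsPerClass = 4, fs = 128, seed = 11,
                      channels = c("CP5", "C3"))
  e3 <- generateErdEpochs(cfgRev)
  expect_identical(epochData(e1)[, 1, ], epochData(e3)[, 2, ])
  expect_identical(epochData(e1)[, 2, ], epochData(e3)[, 1, ])
})

test_that("erdDepth = 0.5 quarters the post-cue alpha power of the fist class", {
  cfg <- erdConfig(nEpochsPerClass = 100, fs = 128, seed = 3, erdDepth = 0.5,
                   chaoticMix = c(open = 0, fist = 0), noiseSigma = 0)
  ep <- generateErdEpochs(cfg)
  cue <- round(0.2 * 128)
  post <- (cue + round(0.15 * 128)):nSamples(ep)   # past the ramp
  pw <- apply(epochData(ep)[, 1, post], 1, function(v) mean(v^2))
  ratio <- mean(pw[epochLabels(ep) == "fist"]) /
    mean(pw[epochLabels(ep) == "open"])
  expect_equal(ratio, 0.25, tolerance = 0.02)
})

test_that("identical class parameters give exchangeable alpha power", {
  cfg <- erdConfig(nEpochsPerClass = 50, fs = 128, seed = 5, erdDepth = 0,
                   chaoticMix = c(open = 0.6, fist = 0.6),
                   chaoticR = c(open = 3.9, fist = 3.9))
  ep <- generateErdEpochs(cfg)
  pw <- apply(epochData(ep)[, 1, ], 1, function(v) mean(v^2))
  p <- t.test(pw[epochLabels(ep) == "open"],
              pw[epochLabels(ep) == "fist"])$p.value
  expect_gt(p, 0.01)
})

test_that("config invariants are enforced", {
  expect_error(erdConfig(erdDepth = 1), "erdDepth")
  expect_error(erdConfig(fs = 50), "fs")
})
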