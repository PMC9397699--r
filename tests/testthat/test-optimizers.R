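test_that("team weights hit the contract endpoints", {
  expect_equal(twWeights(c(10, 0)), c(1, 2))
  expect_equal(twWeights(c(4, 2, 0)), c(1, 1.5, 2))
  expect_equal(twWeights(c(3, 3, 3)), c(1.5, 1.5, 1.5))
  expect_error(twWeights(c(1, NA)), "non-finite")
  # maximization orientation flips the ranking
  expect_equal(twWeights(c(10, 0), minimize = FALSE), c(2, 1))
})

test_that("weights lie in [1,2] with unique extremes for distinct fitnesses", {
  set.seed(1)
  for (i in 1:20) {
    f <- rnorm(8)
    w <- twWeights(f)
    expect_true(all(w >= 1 & w <= 2))
    expect_equal(sum(w == 2), 1)
    expect_equal(sum(w == 1), 1)
  }
})

test_that("initialization spans the box and honors degenerate rand streams", {
  sp <- searchSpace(c(-2, 0), c(4, 10))
  expect_true(all(twInitialize(sp, 5, randFn = function(n) rep(0, n)) ==
                  matrix(sp$lb, 5, 2, byrow = TRUE)))
  expect_true(all(twInitialize(sp, 5, randFn = function(n) rep(1, n)) ==
                  matrix(sp$ub, 5, 2, byrow = TRUE)))
  expect_identical(twInitialize(sp, 6, seed = 9), twInitialize(sp, 6, seed = 9))
})

test_that("with equal weights motion is pure stochastic perturbation", {
  sp <- searchSpace(c(-1, -1), c(1, 1))
  X <- rbind(c(0.5, -0.5), c(-0.2, 0.1))
  cfg <- twConfig(N = 2, alpha = 0.5, maxEvaluations = 10)
  # equal fitness -> equal weights -> zero pulling force; kill the noise too
  teams <- list(X = X, F = c(1, 1))
  out <- twStep(teams, sp, cfg, function(x) 1, iteration = 1,
                factorFn = function(n) rep(0, n))
  expect_equal(out$X, X)
})

test_that("the heavier team pulls the lighter strictly toward it", {
  sp <- searchSpace(-5, 5)
  teams <- list(X = matrix(c(-2, 3), 2, 1), F = c(5, 1))  # team 2 is better
  cfg <- twConfig(N = 2, maxEvaluations = 10)
  out <- twStep(teams, sp, cfg, function(x) sum(x^2), iteration = 1,
                factorFn = function(n) rep(0, n))
  expect_gt(out$X[1, 1], -2)         # moved toward +3
  expect_equal(out$X[2, 1], 3)       # best team feels no pull
})

test_that("chaotic and uniform variants reduce to the same step bitwise", {
  sp <- searchSpace(c(-5, -5), c(5, 5))
  set.seed(3)
  X <- twInitialize(sp, 6, seed = 3)
  teams <- list(X = X, F = apply(X, 1, sphereFn))
  cfg <- twConfig(N = 6, maxEvaluations = 100)
  constMap <- chaoticMapState(function(x) 0.37)
  a <- ctwStep(teams, sp, cfg, sphereFn, constMap, iteration = 2)
  b <- twStep(teams, sp, cfg, sphereFn, iteration = 2,
              factorFn = function(n) rep(2 * 0.37 - 1, n))
  expect_identical(a$X, b$X)
  expect_identical(a$F, b$F)
})

test_that("every chaotic map emits long non-collapsing orbits inside (0,1)", {
  for (m in chaoticMapNames()) {
    s <- chaoticMapSequence(m, 2e4)
    expect_true(all(s > 0 & s < 1), info = m)
    expect_gt(length(unique(round(s, 8))), 100, label = m)
  }
})

test_that("logistic map emits the exact hand-iterated values", {
  expect_equal(chaoticMapSequence("logistic", 3, 0.7),
               c(0.84, 0.5376, 0.99434496), tolerance = 1e-10)
})

test_that("orbit collapse onto a fixed point raises an error", {
  expect_error(chaoticMapSequence("logistic", 50, 0.75), "collapsed")
  expect_error(chaoticMapSequence("gauss_mouse", 50, 0.5), "collapsed")
})

test_that("logistic map orbit is far from uniform (U-shaped density)", {
  s <- chaoticMapSequence("logistic", 1e5)
  ks <- max(abs(sort(s) - (seq_along(s) - 0.5) / length(s)))
  expect_gt(ks, 0.1)
})

test_that("the evaluation budget is a hard cap, verified by counting", {
  cnt <- 0L
  f <- function(x) { cnt <<- cnt + 1L; sum(x^2) }
  sp <- searchSpace(c(-5, -5), c(5, 5))
  for (m in c("tw", "ctw", "random")) {
    cnt <- 0L
    res <- runOptimizer(f, sp, m, twConfig(N = 10, seed = 1,
                                           maxEvaluations = 100))
    expect_lte(cnt, 100)
    expect_equal(res@evaluations, cnt)
  }
  cnt <- 0L
  res <- iwdOptimize(f, list(seq(-5, 5, 1), seq(-5, 5, 1)),
                     iwdConfig(seed = 1, maxEvaluations = 100))
  expect_lte(cnt, 100)
})

test_that("best-so-far history is monotone and positions stay in the box", {
  sp <- searchSpace(c(-5, -5), c(5, 5))
  res <- runOptimizer(sphereFn, sp, "ctw",
                      twConfig(N = 8, seed = 2, maxEvaluations = 400))
  expect_true(all(diff(res@history$best) <= 0))
  expect_true(all(res@bestX >= sp$lb & res@bestX <= sp$ub))
})

test_that("constant fitness returns an initial point with a flat history", {
  sp <- searchSpace(-1, 1)
  res <- runOptimizer(function(x) 7, sp, "tw",
                      twConfig(N = 5, seed = 1, maxEvaluations = 50))
  expect_equal(res@bestF, 7)
  expect_true(all(res@history$best == 7))
})

test_that("non-finite fitness is treated as worst with a warning", {
  sp <- searchSpace(-1, 1)
  ws <- capture_warnings(
    res <- runOptimizer(function(x) if (x[1] > 0) NaN else sum(x^2), sp,
                        "random", twConfig(seed = 5, maxEvaluations = 30)))
  expect_true(any(grepl("non-finite", ws)))
  expect_true(is.finite(res@bestF))
})

test_that("IWD recovers a single-layer optimum quickly on all seeds", {
  ok <- vapply(1:20, function(r) {
    res <- iwdOptimize(function(x) abs(x - 3), list(1:5),
                       iwdConfig(seed = r, nDrops = 5, maxEvaluations = 250))
    res@bestX == 3
  }, logical(1))
  expect_true(all(ok))
})

test_that("with soil updates disabled edge choice is uniform", {
  counts <- integer(5)
  f <- function(x) { counts[x] <<- counts[x] + 1L; 0 }
  iwdOptimize(f, list(1:5),
              iwdConfig(seed = 8, nDrops = 20, rhoN = 0, rhoIwd = 0,
                        epsilon = 0, maxEvaluations = 4000))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("integer-masked coordinates are rounded at evaluation time only", {
  seen <- NULL
  f <- function(x) { seen <<- rbind(seen, x); sum(x^2) }
  sp <- searchSpace(c(0, 0), c(10, 10), integerMask = c(TRUE, FALSE))
  runOptimizer(f, sp, "random", twConfig(seed = 1, maxEvaluations = 25))
  expect_true(all(seen[, 1] == round(seen[, 1])))
  expect_false(all(seen[, 2] == round(seen[, 2])))
})

test_that("benchmark harness tabulates non-negative errors and handles reps=0", {
  expect_equal(nrow(benchmarkSuite(reps = 0)), 0)
  tab <- benchmarkSuite(methods = "ctw", functions = c("sphere", "rastrigin"),
                        reps = 2, budget = 300)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$medianError >= 0))
  expect_equal(length(benchmarkNames()), 10)
})
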