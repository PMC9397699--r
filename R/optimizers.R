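#' @include classes.R
NULL

#' Define a box-constrained search space
#'
#' @param lb,ub per-coordinate lower/upper bounds (lb < ub elementwise).
#' @param integerMask logical per coordinate; masked coordinates are rounded
#'   to integers at fitness-evaluation time while the population search stays
#'   continuous.
#' @return A list of class `SearchSpace`.
#' @export
searchSpace <- function(lb, ub, integerMask = NULL) {
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(ub) != length(lb)) stop("lb and ub must have equal length")
  if (!all(lb < ub)) stop("need lb < ub elementwise")
  if (is.null(integerMask)) integerMask <- rep(FALSE, length(lb))
  structure(list(lb = lb, ub = ub, d = length(lb),
                 integerMask = integerMask), class = "SearchSpace")
}

#' Configuration for the Tug-of-War optimizers
#'
#' @param N number of teams (population size).
#' @param alpha proportional factor of the stochastic term; the term is
#'   scaled by `alpha^k` at iteration k, so `alpha` < 1 anneals exploration.
#' @param beta stochastic-term factor in (0, 1) (plain TW only; the chaotic
#'   variant draws its factor from the map instead).
#' @param mu friction-like coefficient in the acceleration denominator.
#' @param dtStep step time in the `0.5 * a * dt^2` displacement term.
#' @param maxEvaluations cost-function evaluation budget (default 10000).
#' @param seed RNG seed.
#' @param mapId chaotic map for the CTW variant (see [chaoticMapNames()]),
#'   or a function(x) giving the next raw map state.
#' @param fitnessMix if TRUE the normalized fitness difference of each team
#'   pair is folded into the chaotic map state before drawing its factor
#'   (the literal reading of the chaotic searching factor as a function of
#'   F_i - F_j); FALSE (default) iterates the map autonomously, which
#'   preserves its ergodicity after the population has converged and
#'   empirically optimizes much better.
#' @return A list of class `TWConfig`.
#' @export
twConfig <- function(N = 20L, alpha = 0.98, beta = 0.1, mu = 1, dtStep = 1,
                     maxEvaluations = 10000L, seed = NULL, mapId = "logistic",
                     fitnessMix = FALSE) {
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  if (maxEvaluations < N) stop("maxEvaluations must be >= N")
  structure(list(N = as.integer(N), alpha = alpha, beta = beta, mu = mu,
                 dtStep = dtStep, maxEvaluations = as.integer(maxEvaluations),
                 seed = seed, mapId = mapId, fitnessMix = fitnessMix),
            class = "TWConfig")
}

#' Initialize a Tug-of-War population uniformly in the box
#'
#' X_i = LB + rand * (UB - LB), one team per row.
#'
#' @param space a [searchSpace()].
#' @param N number of teams.
#' @param seed RNG seed (NULL = ambient stream).
#' @param randFn optional override of the uniform source (for testing
#'   degenerate streams); a function(n) returning n values in [0, 1].
#' @return N x d matrix of positions.
#' @export
twInitialize <- function(space, N, seed = NULL, randFn = runif) {
  withSeed(seed, function() {
    r <- matrix(randFn(N * space$d), N, space$d)
    sweep(sweep(r, 2, space$ub - space$lb, "*"), 2, space$lb, "+")
  })
}

#' Fitness-proportional team weights
#'
#' W_i = (F_i - F_worst) / (F_best - F_worst) + 1: the best team gets weight
#' 2, the worst weight 1, the rest affine in between. With all fitnesses
#' equal every weight is 1.5 by convention.
#'
#' @param fitnesses fitness values (finite).
#' @param minimize if TRUE (default) smaller fitness is better.
#' @return Numeric weights in [1, 2].
#' @export
twWeights <- function(fitnesses, minimize = TRUE) {
  if (!all(is.finite(fitnesses))) stop("non-finite fitness values")
  best <- if (minimize) min(fitnesses) else max(fitnesses)
  worst <- if (minimize) max(fitnesses) else min(fitnesses)
  if (best == worst) return(rep(1.5, length(fitnesses)))
  (fitnesses - worst) / (best - worst) + 1
}

# Shared TW/CTW displacement: for each ordered pair (i, j),
#   g_ij = X_j - X_i,   F_p,ij = max(W_i mu, W_j mu),
#   F_r,ij = F_p,ij - W_i mu   (zero when i is the heavier team),
#   a_ij = g_ij * F_r,ij / (W_i mu),
#   dX_ij = 0.5 a_ij dt^2 + alpha^k * s_ij * (UB - LB),
# where the signed stochastic factor s_ij comes from `factorFn` (one value
# per pair and coordinate): beta * (2 rand - 1) for TW, (2 xi - 1) with xi a
# chaotic map iterate for CTW. The term is centred so exploration is
# two-sided, and annealed by alpha^k.
# `factors` is a (N*(N-1)) x d matrix of signed stochastic factors, rows in
# the order (i=1: all j != 1), (i=2: all j != 2), ...
twCore <- function(X, W, space, config, iteration, factors) {
  N <- nrow(X); d <- ncol(X)
  span <- space$ub - space$lb
  scale <- config$alpha^iteration
  Wmu <- W * config$mu
  FR <- config$mu * outer(W, W, function(wi, wj) pmax(0, wj - wi))  # F_r,ij
  pull <- (FR %*% X - rowSums(FR) * X) / Wmu
  noise <- rowsum(factors, group = rep(seq_len(N), each = N - 1L))
  dimnames(noise) <- NULL
  delta <- 0.5 * pull * config$dtStep^2 +
    scale * sweep(noise, 2, span, "*")
  newX <- X + delta
  newX <- pmin(pmax(newX, matrix(space$lb, N, d, byrow = TRUE)),
               matrix(space$ub, N, d, byrow = TRUE))
  newX
}

# Iterate a chaotic map n times, emitting normalized values, in one call.
mapNextN <- function(state, n) {
  out <- numeric(n)
  x <- state$x; stepFn <- state$step
  lo <- state$domain[1]; hi <- state$domain[2]
  for (i in seq_len(n)) {
    x <- stepFn(x)
    out[i] <- (x - lo) / (hi - lo)
  }
  state$x <- x
  pmin(pmax(out, 1e-12), 1 - 1e-12)
}

#' One Tug-of-War generation
#'
#' Computes every team's displacement from all pairwise pulls plus the
#' annealed stochastic term, clamps to the box, and evaluates the new
#' positions. Teams keep their previous position when the new fitness is
#' worse for the current best team (elitism), so the pull target never
#' degrades.
#'
#' @param teams list with elements `X` (N x d positions) and `F` (fitness).
#' @param space a [searchSpace()].
#' @param config a [twConfig()].
#' @param fitnessFn vectorizable fitness function of one position vector.
#' @param iteration iteration counter k (enters the alpha^k annealing).
#' @param factorFn signed stochastic factor source, function(n) -> n values
#'   in (-1, 1); defaults to `beta * (2 * runif(n) - 1)` (plain TW).
#' @return Updated `teams` list; attribute "evals" counts fitness calls.
#' @export
twStep <- function(teams, space, config, fitnessFn, iteration = 1L,
                   factorFn = NULL) {
  if (is.null(factorFn))
    factorFn <- function(n) config$beta * (2 * runif(n) - 1)
  W <- twWeights(teams$F)
  N <- nrow(teams$X); d <- ncol(teams$X)
  factors <- matrix(factorFn(N * (N - 1L) * d), N * (N - 1L), d)
  newX <- twCore(teams$X, W, space, config, iteration, factors)
  newF <- apply(newX, 1, fitnessFn)
  bestOld <- which.min(teams$F)
  if (newF[bestOld] > teams$F[bestOld]) {   # elitist guard for the best team
    newX[bestOld, ] <- teams$X[bestOld, ]
    newF[bestOld] <- teams$F[bestOld]
  }
  structure(list(X = newX, F = newF), evals = nrow(newX))
}

#' One Chaotic Tug-of-War generation
#'
#' Identical to [twStep()] except that the stochastic factors are iterates
#' of a chaotic map (ergodic, non-repeating) instead of uniform draws; the
#' normalized fitness difference of the interacting pair is folded into the
#' map state when `config$fitnessMix` is TRUE.
#'
#' @inheritParams twStep
#' @param mapState a chaotic map state from [chaoticMapState()].
#' @return Updated `teams` list; attribute "evals" counts fitness calls.
#' @export
ctwStep <- function(teams, space, config, fitnessFn, mapState,
                    iteration = 1L) {
  W <- twWeights(teams$F)
  N <- nrow(teams$X); d <- ncol(teams$X)
  if (config$fitnessMix) {
    # literal chaotic searching factor: fold each pair's normalized fitness
    # difference into the map state before drawing that pair's factors
    span <- diff(range(teams$F))
    pairDiffs <- abs(outer(teams$F, teams$F, "-"))
    if (span > 0) pairDiffs <- pairDiffs / span
    # row order must match twCore: (i, all j != i) by increasing j
    pq <- as.vector(t(pairDiffs))[as.vector(t(row(pairDiffs) != col(pairDiffs)))]
    factors <- matrix(0, N * (N - 1L), d)
    for (p in seq_len(nrow(factors))) {
      mapMix(mapState, pq[p])
      factors[p, ] <- 2 * mapNextN(mapState, d) - 1
    }
  } else {
    factors <- matrix(2 * mapNextN(mapState, N * (N - 1L) * d) - 1,
                      N * (N - 1L), d)
  }
  newX <- twCore(teams$X, W, space, config, iteration, factors)
  newF <- apply(newX, 1, fitnessFn)
  bestOld <- which.min(teams$F)
  if (newF[bestOld] > teams$F[bestOld]) {
    newX[bestOld, ] <- teams$X[bestOld, ]
    newF[bestOld] <- teams$F[bestOld]
  }
  structure(list(X = newX, F = newF), evals = nrow(newX))
}

## ---- chaotic map library ----------------------------------------------

chaoticMapDefs <- list(
  chebyshev = list(x0 = 0.7, domain = c(-1, 1),
                   step = function(x) cos(4 * acos(pmin(pmax(x, -1), 1)))),
  circle = list(x0 = 0.7, domain = c(0, 1),
                step = function(x) (x + 0.2 - (0.5 / (2 * pi)) * sin(2 * pi * x)) %% 1),
  # rational seeds terminate (continued fraction) -> irrational-ish default
  gauss_mouse = list(x0 = 0.5772156649, domain = c(0, 1),
                     step = function(x) if (x == 0) 0 else (1 / x) %% 1),
  intermittency = list(x0 = 0.55, domain = c(0, 1),
    step = function(x) {
      P <- 0.5; eps <- 0.001; c0 <- (1 - eps - P) / P^2
      if (x <= P) eps + x + c0 * x^2 else (x - P) / (1 - P)
    }),
  iterative = list(x0 = 0.7, domain = c(-1, 1),
                   step = function(x) sin(0.7 * pi / x)),
  liebovitch = list(x0 = 0.4, domain = c(0, 1),
    step = function(x) {
      P1 <- 0.3; P2 <- 0.6
      a <- P2 / P1 * (1 - (P2 - P1))
      b <- 1 / (P2 - 1) * ((P2 - 1) - P1 * (P2 - P1))
      if (x <= P1) a * x
      else if (x <= P2) (P2 - x) / (P2 - P1)
      else 1 - b * (1 - x)
    }),
  logistic = list(x0 = 0.7, domain = c(0, 1), step = function(x) 4 * x * (1 - x)),
  piecewise = list(x0 = 0.7, domain = c(0, 1),
    step = function(x) {
      P <- 0.4
      if (x < P) x / P
      else if (x < 0.5) (x - P) / (0.5 - P)
      else if (x < 1 - P) (1 - P - x) / (0.5 - P)
      else (1 - x) / P
    }),
  sine = list(x0 = 0.7, domain = c(0, 1), step = function(x) sin(pi * x)),
  singer = list(x0 = 0.7, domain = c(0, 1),
    step = function(x) 1.07 * (7.86 * x - 23.31 * x^2 + 28.75 * x^3 -
                               13.302875 * x^4)),
  sinusoidal = list(x0 = 0.7, domain = c(0, 1),
                    step = function(x) 2.3 * x^2 * sin(pi * x)),
  # 0.7-breakpoint tent: the symmetric mu=2 tent is numerically degenerate
  # in binary floating point (every dyadic orbit reaches 0)
  tent = list(x0 = 0.6, domain = c(0, 1),
              step = function(x) if (x < 0.7) x / 0.7 else (10 / 3) * (1 - x))
)

#' Names of the twelve built-in chaotic maps
#' @return Character vector of map identifiers.
#' @export
chaoticMapNames <- function() names(chaoticMapDefs)

#' Create an iterable chaotic map state
#'
#' @param mapId one of [chaoticMapNames()], or a function(x) returning the
#'   next raw state (custom maps; assumed to live in (0, 1)).
#' @param x0 initial state in the map's raw domain (default per map).
#' @return An environment holding the evolving state.
#' @export
chaoticMapState <- function(mapId = "logistic", x0 = NULL) {
  if (is.function(mapId)) {
    def <- list(x0 = if (is.null(x0)) 0.7 else x0, domain = c(0, 1),
                step = mapId)
  } else {
    def <- chaoticMapDefs[[match.arg(mapId, names(chaoticMapDefs))]]
    if (!is.null(x0)) def$x0 <- x0
  }
  e <- new.env(parent = emptyenv())
  e$x <- def$x0; e$step <- def$step; e$domain <- def$domain
  e
}

# Advance the map one step and emit a value normalized into (0, 1).
mapNext <- function(state) {
  state$x <- state$step(state$x)
  lo <- state$domain[1]; hi <- state$domain[2]
  u <- (state$x - lo) / (hi - lo)
  min(max(u, 1e-12), 1 - 1e-12)
}

# Fold an exogenous value in [0, 1] into the map state (additively, mod 1,
# in the normalized domain).
mapMix <- function(state, v) {
  lo <- state$domain[1]; hi <- state$domain[2]
  u <- (state$x - lo) / (hi - lo)
  u <- (u + v) %% 1
  u <- min(max(u, 1e-12), 1 - 1e-12)
  state$x <- lo + u * (hi - lo)
  invisible(state)
}

#' Generate a normalized chaotic map sequence
#'
#' Iterates the requested map `n` times from `x0`, emitting each state
#' min-max normalized into (0, 1). Orbits that collapse onto a fixed point
#' or a short cycle (non-chaotic seed) raise an error suggesting a new x0.
#'
#' @param mapId one of [chaoticMapNames()].
#' @param n number of iterates.
#' @param x0 initial state (default per map).
#' @return Numeric vector of n values in (0, 1).
#' @examples
#' chaoticMapSequence("logistic", 3, x0 = 0.7)  # 0.84, 0.5376, 0.9943
#' @export
chaoticMapSequence <- function(mapId, n, x0 = NULL) {
  state <- chaoticMapState(mapId, x0)
  out <- vapply(seq_len(n), function(i) mapNext(state), numeric(1))
  tailPart <- utils::tail(out, min(n, 64L))
  if (length(unique(round(tailPart, 12))) <= 2L)
    stop(sprintf("orbit of map '%s' collapsed to a fixed point or short cycle; choose a different x0",
                 if (is.character(mapId)) mapId else "custom"))
  out
}

## ---- Intelligent Water Drop -------------------------------------------

#' Configuration for the Intelligent Water Drop optimizer
#'
#' Standard IWD constants: velocity update a_v/(b_v + c_v soil^2), soil
#' update a_s/(b_s + c_s time^2) with unit edge length, local soil rate
#' rho_n and global (best-path) rate rho_iwd.
#'
#' @param nDrops drops per iteration.
#' @param av,bv,cv velocity-update coefficients.
#' @param as_,bs,cs soil-update coefficients.
#' @param rhoN local soil update rate in (0, 1).
#' @param rhoIwd global soil update rate in (0, 1).
#' @param soilInit,velocityInit initial edge soil and drop velocity.
#' @param epsilon per-layer exploration probability: with probability
#'   `epsilon` a drop picks a uniform random candidate in a layer instead of
#'   the soil-guided choice, so the search never freezes on the incumbent
#'   path.
#' @param maxEvaluations fitness-evaluation budget.
#' @param seed RNG seed.
#' @return A list of class `IWDConfig`.
#' @export
iwdConfig <- function(nDrops = 20L, av = 1, bv = 0.01, cv = 1, as_ = 1,
                      bs = 0.01, cs = 1, rhoN = 0.05, rhoIwd = 0.9,
                      soilInit = 10000, velocityInit = 200, epsilon = 0.15,
                      maxEvaluations = 10000L, seed = NULL) {
  if (rhoN < 0 || rhoN >= 1 || rhoIwd < 0 || rhoIwd >= 1)
    stop("rhoN and rhoIwd must lie in [0, 1); 0 disables the update")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  structure(list(nDrops = as.integer(nDrops), av = av, bv = bv, cv = cv,
                 as_ = as_, bs = bs, cs = cs, rhoN = rhoN, rhoIwd = rhoIwd,
                 soilInit = soilInit, velocityInit = velocityInit,
                 epsilon = epsilon,
                 maxEvaluations = as.integer(maxEvaluations), seed = seed),
            class = "IWDConfig")
}

#' Intelligent Water Drop search over a layered candidate graph
#'
#' One layer per decision variable; each drop builds a path by choosing one
#' candidate per layer with probability inversely monotone in the soil of
#' the incoming edge, gaining velocity on low-soil edges and eroding the
#' soil it traverses. After each iteration the best path's soil is reduced
#' globally, concentrating later drops. Fitness calls are capped by the
#' budget; the best path ever evaluated is returned.
#'
#' @param fitnessFn function of one numeric vector (one value per layer).
#' @param layeredCandidates list of numeric vectors (candidate values per
#'   layer).
#' @param config an [iwdConfig()].
#' @return An [OptimizationResult-class].
#' @export
iwdOptimize <- function(fitnessFn, layeredCandidates, config = iwdConfig()) {
  if (any(vapply(layeredCandidates, length, 1L) == 0L))
    stop("every layer needs at least one candidate")
  withSeed(config$seed, function() {
    L <- length(layeredCandidates)
    sizes <- vapply(layeredCandidates, length, 1L)
    # soil per layer: incoming-edge soil aggregated per node (layered graph
    # with full connections is equivalent to per-node soil per layer)
    soil <- lapply(sizes, function(k) rep(config$soilInit, k))
    evals <- 0L
    bestF <- Inf; bestIdx <- NULL; bestCarried <- 0
    histBest <- numeric(config$maxEvaluations)
    repeat {
      if (evals + 1L > config$maxEvaluations) break
      for (dr in seq_len(config$nDrops)) {
        if (evals + 1L > config$maxEvaluations) break
        vel <- config$velocityInit
        soilCarried <- 0
        idx <- integer(L)
        for (l in seq_len(L)) {
          s <- soil[[l]]
          if (runif(1) < config$epsilon) {
            idx[l] <- sample.int(sizes[l], 1L)      # exploration draw
          } else {
            g <- if (min(s) >= 0) s else s - min(s)
            f <- 1 / (0.01 + g)
            idx[l] <- sample.int(sizes[l], 1L, prob = f / sum(f))
          }
          vel <- vel + config$av / (config$bv + config$cv * s[idx[l]]^2)
          tEdge <- 1 / max(vel, 1e-9)
          dSoil <- config$as_ / (config$bs + config$cs * tEdge^2)
          soilCarried <- soilCarried + dSoil
          # subtractive erosion: soil removed is carried away by the drop
          soil[[l]][idx[l]] <- s[idx[l]] - config$rhoN * dSoil
        }
        x <- mapply(function(cand, i) cand[i], layeredCandidates, idx)
        Fv <- fitnessFn(as.numeric(x))
        evals <- evals + 1L
        if (!is.finite(Fv)) Fv <- Inf
        if (Fv < bestF) {
          bestF <- Fv; bestIdx <- idx; bestCarried <- soilCarried
          # relocation: a newly found best path immediately takes over as the
          # soil minimum of every layer, else a long-eroded incumbent keeps
          # attracting the drops no matter what was just discovered
          for (l in seq_len(L)) {
            soil[[l]][idx[l]] <- min(soil[[l]]) -
              config$rhoIwd * soilCarried / L
          }
        }
        histBest[evals] <- bestF
      }
      # global update: erode the soil along the best path found so far
      # (elitist), spreading the best drop's carried soil across its layers;
      # quality feedback accumulates here every iteration, so it eventually
      # dominates the quality-blind local erosion of merely popular nodes
      if (!is.null(bestIdx)) {
        for (l in seq_len(L)) {
          soil[[l]][bestIdx[l]] <- soil[[l]][bestIdx[l]] -
            config$rhoIwd * bestCarried / L
        }
      }
      if (evals + 1L > config$maxEvaluations) break
    }
    bestX <- mapply(function(cand, i) cand[i], layeredCandidates, bestIdx)
    new("OptimizationResult", bestX = as.numeric(bestX), bestF = bestF,
        evaluations = evals,
        history = data.frame(eval = seq_len(evals), best = histBest[seq_len(evals)]),
        method = "iwd")
  })
}

## ---- unified front end -------------------------------------------------

#' Run a budgeted metaheuristic on a box-constrained fitness function
#'
#' Minimizes `fitnessFn` with the requested method under a hard cap on
#' cost-function evaluations. Integer-masked coordinates are rounded at
#' evaluation time only. Non-finite fitness values are treated as worst and
#' logged with a warning. Reproducible from `config$seed`.
#'
#' @param fitnessFn function of one numeric vector.
#' @param space a [searchSpace()].
#' @param method "tw", "ctw", "iwd" or "random".
#' @param config a [twConfig()] (tw/ctw/random) or [iwdConfig()] (iwd).
#' @param gridPoints candidates per coordinate when the layered IWD graph is
#'   built from a continuous box (default 101, includes the midpoint).
#' @return An [OptimizationResult-class] with the best point, its fitness,
#'   the evaluation count and the best-so-far history.
#' @export
runOptimizer <- function(fitnessFn, space, method = c("tw", "ctw", "iwd", "random"),
                         config = twConfig(), gridPoints = 101L) {
  method <- match.arg(method)
  wrapped <- function(x) {
    if (any(space$integerMask)) x[space$integerMask] <- round(x[space$integerMask])
    v <- fitnessFn(x)
    if (!is.finite(v)) {
      warning("non-finite fitness treated as worst at x = ",
              paste(signif(x, 4), collapse = ", "), call. = FALSE)
      v <- Inf
    }
    v
  }
  if (method == "iwd") {
    if (!inherits(config, "IWDConfig")) config <- iwdConfig(seed = config$seed,
      maxEvaluations = config$maxEvaluations)
    layers <- lapply(seq_len(space$d), function(i) {
      g <- seq(space$lb[i], space$ub[i], length.out = gridPoints)
      if (space$integerMask[i]) g <- unique(round(g))
      g
    })
    return(iwdOptimize(wrapped, layers, config))
  }
  withSeed(config$seed, function() {
    budget <- config$maxEvaluations
    evals <- 0L
    histBest <- numeric(budget)
    bestF <- Inf; bestX <- NULL
    counting <- function(x) {
      evals <<- evals + 1L
      v <- wrapped(x)
      if (v < bestF) { bestF <<- v; bestX <<- x }
      histBest[evals] <<- bestF
      v
    }
    if (method == "random") {
      while (evals < budget) {
        x <- space$lb + runif(space$d) * (space$ub - space$lb)
        counting(x)
      }
    } else {
      X <- twInitialize(space, config$N, seed = NULL)
      Fv <- apply(X, 1, counting)
      teams <- list(X = X, F = Fv)
      mapState <- if (method == "ctw") chaoticMapState(config$mapId) else NULL
      k <- 0L
      while (evals + config$N <= budget) {   # partial steps rejected
        k <- k + 1L
        teams <- if (method == "ctw")
          ctwStep(teams, space, config, counting, mapState, iteration = k)
        else twStep(teams, space, config, counting, iteration = k)
      }
    }
    new("OptimizationResult", bestX = as.numeric(bestX), bestF = bestF,
        evaluations = evals,
        history = data.frame(eval = seq_len(evals),
                             best = histBest[seq_len(evals)]),
        method = method)
  })
}

## ---- benchmark suite ---------------------------------------------------

benchmarkDefs <- list(
  sphere = list(lb = -5.12, ub = 5.12, fmin = 0,
                fn = function(x) sum(x^2)),
  rosenbrock = list(lb = -2.048, ub = 2.048, fmin = 0,
    fn = function(x) sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)),
  rastrigin = list(lb = -5.12, ub = 5.12, fmin = 0,
    fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))),
  ackley = list(lb = -32.768, ub = 32.768, fmin = 0,
    fn = function(x) -20 * exp(-0.2 * sqrt(mean(x^2))) -
      exp(mean(cos(2 * pi * x))) + 20 + exp(1)),
  griewank = list(lb = -600, ub = 600, fmin = 0,
    fn = function(x) sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1),
  schwefel222 = list(lb = -10, ub = 10, fmin = 0,
    fn = function(x) sum(abs(x)) + prod(abs(x))),
  levy = list(lb = -10, ub = 10, fmin = 0,
    fn = function(x) {
      w <- 1 + (x - 1) / 4; n <- length(x)
      sin(pi * w[1])^2 +
        sum((w[-n] - 1)^2 * (1 + 10 * sin(pi * w[-n] + 1)^2)) +
        (w[n] - 1)^2 * (1 + sin(2 * pi * w[n])^2)
    }),
  zakharov = list(lb = -5, ub = 10, fmin = 0,
    fn = function(x) {
      s <- sum(0.5 * seq_along(x) * x)
      sum(x^2) + s^2 + s^4
    }),
  sumsquares = list(lb = -10, ub = 10, fmin = 0,
    fn = function(x) sum(seq_along(x) * x^2)),
  michalewicz = list(lb = 0, ub = pi, fmin = -1.8013,  # 2-D reference minimum
    fn = function(x) -sum(sin(x) * sin(seq_along(x) * x^2 / pi)^20))
)

#' Names of the built-in benchmark functions
#' @return Character vector.
#' @export
benchmarkNames <- function() names(benchmarkDefs)

#' Look up a benchmark function definition
#'
#' @param name one of [benchmarkNames()].
#' @param d dimensionality.
#' @return list with `fn`, `space` (a [searchSpace()]) and `fmin`.
#' @export
benchmarkFunction <- function(name, d = 2L) {
  def <- benchmarkDefs[[match.arg(name, names(benchmarkDefs))]]
  list(fn = def$fn, space = searchSpace(rep(def$lb, d), rep(def$ub, d)),
       fmin = def$fmin)
}

#' Compare optimizers across the standard benchmark suite
#'
#' Runs every (method, function) combination `reps` times at a fixed
#' evaluation budget and tabulates the median and interquartile range of the
#' final error (best fitness minus the known minimum, always >= 0).
#'
#' @param methods subset of c("tw", "ctw", "iwd", "random").
#' @param functions subset of [benchmarkNames()].
#' @param reps repetitions per combination (0 gives an empty table).
#' @param budget evaluation budget per run.
#' @param d dimensionality.
#' @param seed base seed; run r of any combination uses seed + r.
#' @param mapId chaotic map for the ctw method.
#' @return data.frame with columns method, fn, medianError, iqrError, reps.
#' @export
benchmarkSuite <- function(methods = c("tw", "ctw"), functions = benchmarkNames(),
                           reps = 5L, budget = 10000L, d = 2L, seed = 1L,
                           mapId = "logistic") {
  out <- data.frame(method = character(0), fn = character(0),
                    medianError = numeric(0), iqrError = numeric(0),
                    reps = integer(0))
  if (reps == 0L) return(out)
  for (m in methods) {
    for (fname in functions) {
      bm <- benchmarkFunction(fname, d)
      errs <- vapply(seq_len(reps), function(r) {
        cfg <- if (m == "iwd") iwdConfig(seed = seed + r, maxEvaluations = budget)
               else twConfig(seed = seed + r, maxEvaluations = budget,
                             mapId = mapId)
        res <- runOptimizer(bm$fn, bm$space, method = m, config = cfg)
        res@bestF - bm$fmin
      }, numeric(1))
      out <- rbind(out, data.frame(method = m, fn = fname,
                                   medianError = median(errs),
                                   iqrError = stats::IQR(errs),
                                   reps = reps))
    }
  }
  out
}
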