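#' @include classes.R
NULL

# Canonical test systems. Maps and analytic flows are deterministic given the
# spec; the Lorenz flow uses a fixed-step RK4 integrator so orbits are exactly
# reproducible.

supportedSystems <- c("logistic", "henon", "lorenz", "sine", "damped_oscillator")

#' Specify a canonical chaotic or regular test system
#'
#' Builds the parameter record for [simulateSeries()] and [lleOracle()].
#' Supported systems and their parameters:
#' \describe{
#'   \item{logistic}{`r` (default 4), scalar map x <- r x (1 - x).}
#'   \item{henon}{`a` (1.4), `b` (0.3); the x-component is returned.}
#'   \item{lorenz}{`sigma` (10), `rho` (28), `beta` (8/3), `dt` (0.01);
#'     fixed-step RK4, x-component returned.}
#'   \item{sine}{`omega` (rad/sample, default 2*pi/64): a pure limit cycle.}
#'   \item{damped_oscillator}{`decay`, `omega` (per unit time), `dt`:
#'     exponentially decaying oscillation, exponent -decay.}
#' }
#'
#' @param system one of `r paste(sprintf('"%s"', supportedSystems), collapse=", ")`.
#' @param parameters named list overriding the defaults above.
#' @param initialState numeric initial state (length 1 for logistic,
#'   2 for henon, 3 for lorenz; ignored for the analytic flows).
#' @param nSamples samples to produce (after discarding the transient).
#' @param transientDiscard leading iterates dropped before recording.
#' @return A list of class `ChaoticSystemSpec`.
#' @export
chaoticSystemSpec <- function(system, parameters = list(), initialState = NULL,
                              nSamples = 1000L, transientDiscard = 0L) {
  system <- match.arg(system, supportedSystems)
  defaults <- switch(system,
    logistic = list(r = 4),
    henon = list(a = 1.4, b = 0.3),
    lorenz = list(sigma = 10, rho = 28, beta = 8 / 3, dt = 0.01),
    sine = list(omega = 2 * pi / 64, phase = 0),
    damped_oscillator = list(decay = 0.3, omega = 2 * pi, dt = 0.05))
  parameters <- modifyList(defaults, parameters)
  if (is.null(initialState)) {
    initialState <- switch(system, logistic = 0.2, henon = c(0.1, 0.1),
                           lorenz = c(1, 1, 1), sine = 0, damped_oscillator = 0)
  }
  nSamples <- as.integer(nSamples); transientDiscard <- as.integer(transientDiscard)
  if (nSamples <= transientDiscard)
    stop("nSamples must exceed transientDiscard")
  if (system == "logistic" &&
      (initialState[1] <= 0 || initialState[1] >= 1))
    stop("logistic initial state must lie in (0, 1)")
  if (system == "lorenz" && parameters$dt <= 0) stop("Lorenz dt must be > 0")
  structure(list(system = system, parameters = parameters,
                 initialState = as.numeric(initialState),
                 nSamples = nSamples, transientDiscard = transientDiscard),
            class = "ChaoticSystemSpec")
}

# One RK4 step of the Lorenz field.
lorenzRK4 <- function(state, p) {
  f <- function(s) c(p$sigma * (s[2] - s[1]),
                     s[1] * (p$rho - s[3]) - s[2],
                     s[1] * s[2] - p$beta * s[3])
  h <- p$dt
  k1 <- f(state); k2 <- f(state + h / 2 * k1)
  k3 <- f(state + h / 2 * k2); k4 <- f(state + h * k3)
  state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate a canonical test-system series
#'
#' Deterministically iterates the requested map or flow and returns the
#' observable (x-component for multivariate systems) after the transient.
#'
#' @param spec a [chaoticSystemSpec()].
#' @return Numeric vector of `nSamples - transientDiscard` values.
#' @examples
#' x <- simulateSeries(chaoticSystemSpec("logistic", list(r = 4), 0.2, 100))
#' @export
simulateSeries <- function(spec) {
  stopifnot(inherits(spec, "ChaoticSystemSpec"))
  n <- spec$nSamples; p <- spec$parameters
  checkFinite <- function(x, step) {
    if (!all(is.finite(x)))
      stop(sprintf("%s diverged to a non-finite value at step %d", spec$system, step))
    x
  }
  out <- switch(spec$system,
    logistic = {
      x <- spec$initialState[1]; xs <- numeric(n)
      for (t in seq_len(n)) { xs[t] <- x; x <- checkFinite(p$r * x * (1 - x), t) }
      xs
    },
    henon = {
      s <- spec$initialState; xs <- numeric(n)
      for (t in seq_len(n)) {
        xs[t] <- s[1]
        s <- checkFinite(c(1 - p$a * s[1]^2 + s[2], p$b * s[1]), t)
      }
      xs
    },
    lorenz = {
      s <- spec$initialState; xs <- numeric(n)
      for (t in seq_len(n)) { xs[t] <- s[1]; s <- checkFinite(lorenzRK4(s, p), t) }
      xs
    },
    sine = sin(p$omega * (seq_len(n) - 1) + p$phase),
    damped_oscillator = {
      tt <- (seq_len(n) - 1) * p$dt
      exp(-p$decay * tt) * sin(p$omega * tt)
    })
  if (spec$transientDiscard > 0) out <- out[-seq_len(spec$transientDiscard)]
  out
}

# Benettin tangent-vector iteration for a 2-D linear flow dx/dt = A x,
# integrated with fixed-step RK4 and renormalized every step.
benettinLinearFlow <- function(A, dt, nSteps) {
  v <- c(1, 0); acc <- 0
  step <- function(v) {
    k1 <- A %*% v; k2 <- A %*% (v + dt / 2 * k1)
    k3 <- A %*% (v + dt / 2 * k2); k4 <- A %*% (v + dt * k3)
    as.numeric(v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  for (i in seq_len(nSteps)) {
    v <- step(v); nv <- sqrt(sum(v^2))
    acc <- acc + log(nv); v <- v / nv
  }
  acc / (nSteps * dt)
}

#' Ground-truth largest Lyapunov exponent of a test system
#'
#' Independent oracle based on Jacobian products: for 1-D maps the orbit
#' average of ln|f'(x)|, for multivariate systems Benettin renormalization of
#' a tangent vector. Units are nats per iteration for maps and nats per unit
#' time for flows. This never touches the divergence-curve estimator it is
#' used to validate.
#'
#' @param spec a [chaoticSystemSpec()].
#' @param nSteps iterations to average over (>= 1e4 recommended for maps).
#' @return The largest Lyapunov exponent (numeric scalar).
#' @examples
#' lleOracle(chaoticSystemSpec("logistic", list(r = 4)))  # ~ log(2)
#' @export
lleOracle <- function(spec, nSteps = 1e5L) {
  stopifnot(inherits(spec, "ChaoticSystemSpec"))
  p <- spec$parameters
  burn <- max(spec$transientDiscard, 1000L)
  switch(spec$system,
    logistic = {
      x <- spec$initialState[1]
      for (i in seq_len(burn)) x <- p$r * x * (1 - x)
      acc <- 0
      for (i in seq_len(nSteps)) {
        d <- abs(p$r * (1 - 2 * x))
        if (!is.finite(log(d))) stop("non-finite derivative in logistic oracle")
        acc <- acc + log(d)
        x <- p$r * x * (1 - x)
      }
      acc / nSteps
    },
    henon = {
      s <- spec$initialState
      for (i in seq_len(burn)) s <- c(1 - p$a * s[1]^2 + s[2], p$b * s[1])
      v <- c(1, 0); acc <- 0
      for (i in seq_len(nSteps)) {
        J <- matrix(c(-2 * p$a * s[1], p$b, 1, 0), 2, 2)
        v <- as.numeric(J %*% v); nv <- sqrt(sum(v^2))
        acc <- acc + log(nv); v <- v / nv
        s <- c(1 - p$a * s[1]^2 + s[2], p$b * s[1])
      }
      acc / nSteps
    },
    lorenz = {
      s <- spec$initialState
      for (i in seq_len(burn)) s <- lorenzRK4(s, p)
      v <- c(1, 0, 0); acc <- 0
      jac <- function(s) matrix(c(-p$sigma, p$rho - s[3], s[2],
                                  p$sigma, -1, s[1],
                                  0, -s[1], -p$beta), 3, 3)
      h <- p$dt
      for (i in seq_len(nSteps)) {
        # RK4 on the variational equation dv/dt = J(s(t)) v, frozen-orbit J
        # updated at substeps via the state integrator
        s2 <- lorenzRK4(s, modifyList(p, list(dt = h / 2)))
        s3 <- lorenzRK4(s, p)
        k1 <- jac(s) %*% v
        k2 <- jac(s2) %*% (v + h / 2 * k1)
        k3 <- jac(s2) %*% (v + h / 2 * k2)
        k4 <- jac(s3) %*% (v + h * k3)
        v <- as.numeric(v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
        nv <- sqrt(sum(v^2)); acc <- acc + log(nv); v <- v / nv
        s <- s3
      }
      acc / (nSteps * h)
    },
    sine = {
      # harmonic oscillator: eigenvalues +/- i omega, largest exponent 0
      A <- matrix(c(0, -p$omega^2, 1, 0), 2, 2)
      benettinLinearFlow(A, dt = 0.01, nSteps = nSteps)
    },
    damped_oscillator = {
      A <- matrix(c(0, -p$omega^2, 1, -2 * p$decay), 2, 2)
      benettinLinearFlow(A, dt = min(p$dt, 0.01), nSteps = nSteps)
    })
}

#' Configuration for the two-class synthetic ERD/ERS epoch generator
#'
#' Describes synthetic motor-imagery epochs: an alpha-band carrier whose
#' amplitude drops after the virtual cue in the "fist" class (event-related
#' desynchronization), a class-dependent chaotic component (logistic-map
#' series with per-class growth rate), and 1/f pink noise.
#'
#' The recording montage and amplifier of a real experiment are not modeled;
#' the default sampling rate (512 Hz) is a conventional headset rate, not a
#' measured one.
#'
#' @param nEpochsPerClass epochs to generate per class.
#' @param fs sampling rate in Hz (>= 100).
#' @param preMs,postMs epoch extent around the virtual cue (ms).
#' @param channels channel names; per-channel signal streams are seeded
#'   independently from (seed, channel name).
#' @param alphaBand carrier frequency range in Hz, default 8-13.
#' @param erdDepth fractional post-cue alpha-amplitude reduction of the
#'   "fist" class, in [0, 1).
#' @param chaoticMix named weights (open, fist) of the unit-variance,
#'   band-limited chaotic component.
#' @param chaoticR named logistic growth rates (open, fist); unequal values
#'   plant a chaoticity difference that LLE features can detect.
#' @param noiseSigma pink-noise standard deviation.
#' @param seed integer RNG seed; the whole epoch set is reproducible from it.
#' @return A list of class `ERDConfig`.
#' @export
erdConfig <- function(nEpochsPerClass = 100L, fs = 512, preMs = 200,
                      postMs = 2500, channels = c("C3", "CP5"),
                      alphaBand = c(8, 13), erdDepth = 0.5,
                      chaoticMix = c(open = 0.6, fist = 0.6),
                      chaoticR = c(open = 3.9, fist = 3.6),
                      noiseSigma = 0.5, seed = 1L) {
  if (erdDepth < 0 || erdDepth >= 1) stop("erdDepth must lie in [0, 1)")
  if (fs < 100) stop("fs must be >= 100 Hz")
  stopifnot(length(alphaBand) == 2L, alphaBand[1] < alphaBand[2])
  structure(list(nEpochsPerClass = as.integer(nEpochsPerClass), fs = fs,
                 preMs = preMs, postMs = postMs, channels = channels,
                 alphaBand = alphaBand, erdDepth = erdDepth,
                 chaoticMix = chaoticMix, chaoticR = chaoticR,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "ERDConfig")
}

# 1/f-amplitude pink noise via spectral shaping of white noise; unit sd.
pinkNoise <- function(n) {
  x <- rnorm(n)
  X <- fft(x)
  freq <- c(1, seq_len(n - 1))          # avoid dividing the DC bin by 0
  freq <- pmin(freq, n - freq + 1)      # symmetric profile keeps y real
  y <- Re(fft(X / sqrt(freq), inverse = TRUE)) / n
  y / sd(y)
}

#' Generate labeled two-class synthetic ERD/ERS epochs
#'
#' Each epoch and channel is an alpha-band sinusoidal carrier (random
#' frequency and phase) times a class-dependent amplitude envelope (the
#' "fist" class is attenuated by `erdDepth` after the virtual cue, with a
#' 100 ms linear ramp), plus a weighted chaotic component, plus pink noise.
#' Channel streams are seeded independently by (seed, channel name), so the
#' content of a channel does not depend on which other channels were
#' requested.
#'
#' The chaotic component is a logistic-map series (class-dependent growth
#' rate) iterated at the sampling rate and band-limited to `alphaBand`, so
#' the planted chaotic dynamics live inside the analysed band and survive
#' the pipeline's bandpass. Because a filtered chaotic observable needs a
#' higher embedding dimension than the bare map, this also makes the
#' embedding ceilings a live parameter of the reconstruction.
#'
#' @param config an [erdConfig()].
#' @return An [EpochSet-class]; "open" epochs first, then "fist".
#' @export
generateErdEpochs <- function(config) {
  stopifnot(inherits(config, "ERDConfig"))
  ns <- round((config$preMs + config$postMs) * config$fs / 1000)
  nPer <- config$nEpochsPerClass
  classes <- c("open", "fist")
  labels <- rep(classes, each = nPer)
  cueAt <- round(config$preMs * config$fs / 1000)  # 0-based cue sample
  rampLen <- max(1L, round(0.1 * config$fs))
  data <- array(0, dim = c(2L * nPer, length(config$channels), ns))
  tIdx <- seq_len(ns) - 1
  bandFilt <- butterBandpassSos(6, config$alphaBand[1], config$alphaBand[2],
                                config$fs)
  for (ci in seq_along(config$channels)) {
    ch <- config$channels[ci]
    data[, ci, ] <- withSeed(stringSeed(config$seed, ch), function() {
      block <- matrix(0, 2L * nPer, ns)
      for (ei in seq_len(2L * nPer)) {
        cls <- labels[ei]
        f0 <- runif(1, config$alphaBand[1], config$alphaBand[2])
        ph <- runif(1, 0, 2 * pi)
        carrier <- sin(2 * pi * f0 * tIdx / config$fs + ph)
        env <- rep(1, ns)
        if (cls == "fist" && config$erdDepth > 0) {
          post <- which(tIdx >= cueAt)
          ramp <- pmin((tIdx[post] - cueAt) / rampLen, 1)
          env[post] <- 1 - config$erdDepth * ramp
        }
        x0 <- runif(1, 0.1, 0.9)
        chaotic <- simulateSeries(chaoticSystemSpec(
          "logistic", list(r = unname(config$chaoticR[cls])), x0,
          nSamples = ns + 50L, transientDiscard = 50L))
        chaotic <- sosZeroPhase(bandFilt, chaotic - mean(chaotic))
        sdc <- sd(chaotic)
        chaotic <- if (sdc > 0) chaotic / sdc else numeric(ns)
        block[ei, ] <- carrier * env +
          config$chaoticMix[cls] * chaotic +
          config$noiseSigma * pinkNoise(ns)
      }
      block
    })
  }
  EpochSet(data, labels, config$fs, config$channels,
           window = c(config$preMs, config$postMs))
}
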