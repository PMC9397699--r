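#' @include classes.R
NULL

#' Mutual information between a series and its lagged copy
#'
#' Estimates MI(lag) = sum_{i,s} Pr_{i,s} log2(Pr_{i,s} / (Pr_i Pr_s)) over an
#' equal-width 2-D histogram of (x_t, x_{t+lag}), for lag = 1..maxLag. The
#' series is range-normalized before binning, so the curve is invariant under
#' affine transforms of the input. Values are in bits and non-negative up to
#' estimator bias.
#'
#' @param x numeric series.
#' @param maxLag largest lag to evaluate (samples).
#' @param nBins histogram bins per axis.
#' @return Numeric vector of length `maxLag`; element k is MI at lag k.
#' @export
mutualInformationCurve <- function(x, maxLag, nBins = 16L) {
  maxLag <- as.integer(maxLag); nBins <- as.integer(nBins)
  n <- length(x)
  if (n <= maxLag + nBins)
    stop("series too short: need length(x) > maxLag + nBins")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant series has zero entropy; MI undefined")
  as.numeric(cppMICurve(as.numeric(x), maxLag, nBins))
}

# Pure-R reference for the histogram MI estimate; cross-checked against the
# compiled path in the test suite.
miCurveR <- function(x, maxLag, nBins = 16L) {
  maxLag <- as.integer(maxLag); nBins <- as.integer(nBins)
  n <- length(x)
  rng <- range(x)
  # equal-width bins on the full range; top edge closed
  bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * nBins) + 1L, nBins)
  vapply(seq_len(maxLag), function(lag) {
    b1 <- bin[1:(n - lag)]; b2 <- bin[(1 + lag):n]
    joint <- tabulate(b1 + nBins * (b2 - 1L), nbins = nBins * nBins)
    joint <- joint / sum(joint)
    p1 <- tabulate(b1, nbins = nBins) / length(b1)
    p2 <- tabulate(b2, nbins = nBins) / length(b2)
    prod <- outer(p1, p2)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / prod[nz]))
  }, numeric(1))
}

#' Select the embedding lag from a mutual-information curve
#'
#' Returns the first local minimum of the curve (MI(k-1) > MI(k) < MI(k+1));
#' if the curve has no interior local minimum, falls back to the global
#' argmin. The result always lies in [1, length(curve)].
#'
#' @param miCurve MI values at lags 1..maxLag (from
#'   [mutualInformationCurve()]).
#' @return Integer lag.
#' @export
selectLag <- function(miCurve) {
  m <- length(miCurve)
  if (m == 0L) stop("empty MI curve")
  if (m >= 3L) {
    for (k in 2:(m - 1L)) {
      if (miCurve[k - 1L] > miCurve[k] && miCurve[k] < miCurve[k + 1L])
        return(k)
    }
  }
  which.min(miCurve)[1L]
}

#' Delay-embed a scalar series into phase space
#'
#' Takens reconstruction: row j of the result is
#' `[x_j, x_{j+lag}, ..., x_{j+(dim-1) lag}]`.
#'
#' @param x numeric series of length N.
#' @param lag embedding lag in samples (>= 1).
#' @param dim embedding dimension (>= 1; dim 1 returns x as a column).
#' @return A [Trajectory-class] with N - (dim-1)*lag points.
#' @examples
#' trajectoryPoints(delayEmbed(1:6, lag = 2, dim = 3))
#' @export
delayEmbed <- function(x, lag, dim) {
  lag <- as.integer(lag); dim <- as.integer(dim)
  n <- length(x)
  m <- n - (dim - 1L) * lag
  if (m <= 0L)
    stop(sprintf("series too short to embed: N=%d <= (dim-1)*lag=%d",
                 n, (dim - 1L) * lag))
  pts <- matrix(0, m, dim)
  for (d in seq_len(dim)) pts[, d] <- x[(1L + (d - 1L) * lag):((d - 1L) * lag + m)]
  new("Trajectory", points = pts, sourceLength = n, lag = lag, dim = dim)
}

# Pure-R reference implementation of the Theiler-excluded nearest-neighbor
# search; the compiled cppNearestNeighbor() is the production path and the
# two are cross-checked in the test suite.
# Squared Euclidean distance matrix between rows of a matrix, with Inf on the
# band |i-j| <= theiler and on the diagonal.
maskedDist2 <- function(pts, theiler) {
  sq <- rowSums(pts^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(pts)
  d2[d2 < 0] <- 0
  m <- nrow(pts)
  for (off in 0:min(theiler, m - 1L)) {
    idx <- seq_len(m - off)
    d2[cbind(idx, idx + off)] <- Inf
    d2[cbind(idx + off, idx)] <- Inf
  }
  d2
}

# Index of nearest neighbor of every row (ties -> smallest index).
nearestNeighbors <- function(d2) max.col(-d2, ties.method = "first")

#' Fraction of false nearest neighbors at a given dimension
#'
#' Kennel criterion: embed at dimension `dim`, find each point's nearest
#' Euclidean neighbor (excluding a Theiler window of `theiler` samples), and
#' flag the pair false if adding the (dim+1)-th coordinate stretches the
#' distance by more than `rtol` relatively, or past `atol` times the
#' attractor size.
#'
#' @param x numeric series.
#' @param lag embedding lag.
#' @param dim dimension under test (>= 1).
#' @param rtol relative-distance threshold (default 15).
#' @param atol attractor-size threshold (default 2).
#' @param theiler Theiler exclusion window in samples (default = lag).
#' @param maxQueries cap on the number of (evenly spaced, deterministic)
#'   query points whose neighbors are tested; the neighbor search itself
#'   always scans every point. Bounds the cost on long series.
#' @return Fraction of false neighbors in [0, 1].
#' @export
falseNearestFraction <- function(x, lag, dim, rtol = 15, atol = 2,
                                 theiler = lag, maxQueries = 150L) {
  lag <- as.integer(lag); dim <- as.integer(dim)
  n <- length(x)
  mNext <- n - dim * lag          # points that still exist at dimension dim+1
  if (mNext < 2L + theiler)
    stop(sprintf(
      "series too short for FNN at dim %d: need length > %d (= (dim+1-1)*lag + theiler + 2)",
      dim, dim * lag + theiler + 2L))
  qs <- if (mNext > maxQueries)
    unique(round(seq(1L, mNext, length.out = maxQueries))) else seq_len(mNext)
  cppFnnFraction(as.numeric(x), lag, dim, rtol, atol, as.integer(theiler),
                 as.integer(qs), sd(x))
}

# Pure-R reference for the FNN fraction; cross-checked against the compiled
# path in the test suite.
fnnFractionR <- function(x, lag, dim, rtol = 15, atol = 2, theiler = lag) {
  lag <- as.integer(lag); dim <- as.integer(dim)
  n <- length(x)
  mNext <- n - dim * lag
  pts <- delayEmbed(x, lag, dim)@points[seq_len(mNext), , drop = FALSE]
  d2 <- maskedDist2(pts, theiler)
  nn <- nearestNeighbors(d2)
  dist0 <- sqrt(d2[cbind(seq_len(mNext), nn)])
  extra <- abs(x[seq_len(mNext) + dim * lag] - x[nn + dim * lag])
  attractorSize <- sd(x)
  ok <- is.finite(dist0) & dist0 > 0
  falseFlag <- (extra[ok] / dist0[ok] > rtol) |
    (sqrt(dist0[ok]^2 + extra[ok]^2) / attractorSize > atol)
  mean(falseFlag)
}

#' Select the embedding dimension by the false-nearest-neighbor criterion
#'
#' Increases the dimension from 2 up to `maxDim` and returns the first
#' dimension whose false-neighbor fraction drops to `threshold` or below;
#' returns `maxDim` if none does (the ceiling is hit). Dimensions are
#' stepped one by one up to 6 and along a geometric ladder beyond (the
#' fraction varies slowly at high dimension, and the ladder caps the cost
#' of series that unfold late or never).
#'
#' @param x numeric series.
#' @param lag embedding lag.
#' @param maxDim dimension-search ceiling (>= 2).
#' @param threshold acceptable false-neighbor fraction (default 0.01).
#' @param rtol,atol,theiler,maxQueries passed to [falseNearestFraction()].
#' @return Integer dimension in [2, maxDim].
#' @export
#' @param earlyExit if TRUE (default), a series whose false-neighbor
#'   fraction stays above 20 times the threshold for three consecutive
#'   dimensions at dim >= 6 is declared noise-like and assigned `maxDim`
#'   without climbing the remaining ladder (a cost guard; such series do
#'   not unfold at any admissible dimension).
#' @export
selectDimension <- function(x, lag, maxDim, threshold = 0.01, rtol = 15,
                            atol = 2, theiler = lag, maxQueries = 150L,
                            earlyExit = TRUE) {
  maxDim <- as.integer(maxDim)
  if (maxDim < 2L) stop("maxDim must be >= 2")
  ladder <- 2L
  while (ladder[length(ladder)] < maxDim) {
    d <- ladder[length(ladder)]
    ladder <- c(ladder, if (d < 6L) d + 1L else as.integer(ceiling(d * 1.25)))
  }
  ladder <- pmin(ladder, maxDim)
  stubborn <- 0L
  for (d in ladder) {
    q <- as.integer(max(80L, min(maxQueries, ceiling(1500 / d))))
    frac <- falseNearestFraction(x, lag, d, rtol = rtol, atol = atol,
                                 theiler = theiler, maxQueries = q)
    if (frac <= threshold) return(d)
    stubborn <- if (frac > 20 * threshold) stubborn + 1L else 0L
    if (earlyExit && d >= 6L && stubborn >= 3L) return(maxDim)
  }
  maxDim
}
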