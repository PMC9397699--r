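#' @include embedding.R
NULL

#' Average log-divergence curve of nearest-neighbor trajectory pairs
#'
#' For every phase-space point, the nearest neighbor at a temporal separation
#' larger than the Theiler window and with nonzero initial separation is
#' paired with it; the Euclidean separation Q_j(i) of each pair is then
#' tracked for i = 0..maxSteps while both trajectories remain defined. The
#' curve records mean_j ln Q_j(i) per step. Under exponential divergence
#' Q(t) = E exp(lle * t), so the initial slope of this curve (per unit time)
#' is the largest Lyapunov exponent.
#'
#' @param traj a [Trajectory-class] (from [delayEmbed()]).
#' @param theiler Theiler exclusion window in samples (default = the
#'   trajectory's lag).
#' @param maxSteps furthest divergence step to track.
#' @param dt seconds per sample (1 for map iterations).
#' @param maxPairs cap on the number of (evenly spaced, deterministic)
#'   reference points paired with a neighbor; the neighbor search scans all
#'   points. Bounds the cost on long trajectories.
#' @return A [DivergenceCurve-class].
#' @export
divergenceCurve <- function(traj, theiler = traj@lag, maxSteps = 30L, dt = 1,
                            maxPairs = 150L) {
  pts <- traj@points
  m <- nrow(pts)
  if (m < theiler + 10L)
    stop(sprintf("trajectory too short (%d points) for theiler window %d",
                 m, theiler))
  qs <- if (m > maxPairs)
    unique(round(seq(1L, m, length.out = maxPairs))) else seq_len(m)
  nnRes <- cppNearestNeighborQ(pts, qs, theiler, TRUE)  # zero separations excluded
  nn <- integer(m); nn[qs] <- nnRes$index
  valid <- logical(m); valid[qs] <- nnRes$index > 0L & is.finite(nnRes$dist)
  if (!any(valid))
    stop(sprintf("no valid neighbor pairs (theiler=%d, %d points)", theiler, m))
  base <- which(valid)
  # Fix the pair set across the whole tracked horizon: pairs that drop out
  # mid-curve would otherwise change the average's composition step by step,
  # which biases the slope for nonstationary (e.g. decaying) signals. The
  # horizon is shortened, if needed, so that at least half the pairs (and no
  # fewer than two) survive it.
  horizon <- m - pmax(base, nn[base])
  hSorted <- sort(horizon, decreasing = TRUE)
  nKeep <- max(2L, ceiling(length(base) / 2))
  effSteps <- min(maxSteps, hSorted[min(nKeep, length(hSorted))])
  keep <- base[horizon >= effSteps]
  if (length(keep) == 0L)
    stop(sprintf("no neighbor pairs survive the divergence horizon (theiler=%d, %d points)",
                 theiler, m))
  dmat <- cppPairTrack(pts, keep, nn[keep], effSteps)
  ok <- rowSums(dmat <= 0) == 0L   # drop pairs that ever collapse to zero
  if (!any(ok)) stop("all neighbor pairs collapsed to zero separation")
  dmat <- dmat[ok, , drop = FALSE]
  steps <- 0:effSteps
  mld <- colMeans(log(dmat))
  md <- colMeans(dmat)
  np <- rep(nrow(dmat), length(steps))
  new("DivergenceCurve", steps = steps, meanLogDist = mld, meanDist = md,
      nPairs = np, dt = dt,
      extent = max(apply(pts, 2, function(v) diff(range(v)))))
}

#' Largest Lyapunov exponent from a divergence curve
#'
#' Least-squares slope of the mean log-distance over the fitted step range,
#' divided by the sample period. When `fitRange` is NULL it is chosen
#' automatically as the steps before the (geometric mean) separation
#' saturates at 50% of the attractor extent; at least three steps are always
#' retained.
#'
#' @param curve a [DivergenceCurve-class].
#' @param fitRange integer (first, last) step of the linear fit, or NULL for
#'   automatic saturation detection.
#' @param saturationFraction separation level, as a fraction of the attractor
#'   extent, regarded as saturated (default 0.5).
#' @return An [LLEResult-class].
#' @export
largestLyapunov <- function(curve, fitRange = NULL, saturationFraction = 0.5) {
  steps <- curve@steps; mld <- curve@meanLogDist
  if (is.null(fitRange)) {
    sat <- which(curve@meanDist > saturationFraction * curve@extent)
    last <- if (length(sat) > 0L) max(min(sat) - 1L, 3L) else length(steps)
    last <- min(last, length(steps))
    fitRange <- c(steps[1L], steps[last])
  }
  fitRange <- as.integer(fitRange)
  sel <- steps >= fitRange[1] & steps <= fitRange[2]
  if (sum(sel) < 3L) stop("fit range must contain at least 3 steps")
  xs <- steps[sel]; ys <- mld[sel]
  if (var(ys) == 0 || var(xs) == 0) stop("degenerate (zero-variance) fit")
  slope <- cov(xs, ys) / var(xs)
  r2 <- cov(xs, ys)^2 / (var(xs) * var(ys))
  new("LLEResult", lle = slope / curve@dt, fitRange = fitRange,
      r2 = r2, curve = curve)
}

#' Largest-Lyapunov-exponent feature of a scalar signal
#'
#' The full single-signal pipeline: mutual-information lag selection, FNN
#' dimension selection (both bounded by the ceilings in `params`), delay
#' embedding, divergence curve, and linear fit. Deterministic given inputs.
#'
#' @param signal numeric series (one epoch, one channel).
#' @param params an [embeddingParams()]; `maxLag`/`maxDim` bound the
#'   parameter selection. If `lag`/`dim` are set they are used directly.
#' @param dt seconds per sample (default 1: exponent per iteration).
#' @param maxSteps divergence steps to track.
#' @return The scalar exponent estimate (nats per second, or per iteration
#'   when dt = 1).
#' @export
lleFeature <- function(signal, params = embeddingParams(), dt = 1,
                       maxSteps = 30L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  lag <- params@lag
  if (is.na(lag)) {
    mi <- stage("mutual-information",
                mutualInformationCurve(signal, params@maxLag, params@nBins))
    lag <- stage("lag-selection", selectLag(mi))
  }
  dim <- params@dim
  if (is.na(dim)) {
    dim <- stage("fnn-dimension",
                 selectDimension(signal, lag, params@maxDim,
                                 threshold = params@fnnFracThreshold,
                                 rtol = params@fnnRtol, atol = params@fnnAtol))
  }
  traj <- stage("delay-embedding", delayEmbed(signal, lag, dim))
  curve <- stage("divergence-curve",
                 divergenceCurve(traj, theiler = lag, maxSteps = maxSteps,
                                 dt = dt))
  stage("lle-fit", largestLyapunov(curve))@lle
}

#' Label-free LLE features under one or more embedding-parameter sets
#'
#' Applies every parameter set in `paramsList` to every epoch and channel,
#' regardless of epoch label: with two channels and two sets each epoch
#' yields four features (columns `lle_<channel>_<set>`). This is how
#' per-class embedding ceilings are used at evaluation time — as parallel
#' feature maps — so no epoch's features ever depend on its own label.
#' Sets that compare equal are computed once. Epochs failing any stage are
#' dropped; more than `maxSkipFraction` skipped raises an error.
#'
#' @param epochs an [EpochSet-class].
#' @param paramsList named list of [embeddingParams()].
#' @param dt seconds per sample; defaults to 1/fs.
#' @param maxSteps divergence steps to track.
#' @param maxSkipFraction largest tolerated fraction of skipped epochs.
#' @return data.frame with columns epoch, label and one feature column per
#'   (channel, parameter set).
#' @export
lleFeatureSets <- function(epochs, paramsList, dt = NULL, maxSteps = 30L,
                           maxSkipFraction = 0.2) {
  if (is.null(dt)) dt <- 1 / samplingRate(epochs)
  stopifnot(length(paramsList) >= 1L)
  if (is.null(names(paramsList)))
    names(paramsList) <- paste0("set", seq_along(paramsList))
  dat <- epochData(epochs)
  nch <- nChannels(epochs)
  sig <- vapply(paramsList, function(p)
    paste(p@maxLag, p@maxDim, p@lag, p@dim, sep = "/"), character(1))
  firstOf <- match(sig, sig)   # compute duplicated sets once
  feats <- vector("list", length(paramsList))
  for (si in seq_along(paramsList)) {
    if (firstOf[si] < si) { feats[[si]] <- feats[[firstOf[si]]]; next }
    f <- matrix(NA_real_, nEpochs(epochs), nch)
    for (ei in seq_len(nEpochs(epochs)))
      for (ci in seq_len(nch))
        f[ei, ci] <- tryCatch(
          lleFeature(dat[ei, ci, ], paramsList[[si]], dt = dt,
                     maxSteps = maxSteps),
          error = function(e) NA_real_)
    feats[[si]] <- f
  }
  all <- do.call(cbind, feats)
  skipped <- apply(all, 1, function(r) any(!is.finite(r)))
  if (mean(skipped) > maxSkipFraction)
    stop(sprintf("%.0f%% of epochs failed feature extraction (limit %.0f%%)",
                 100 * mean(skipped), 100 * maxSkipFraction))
  out <- data.frame(epoch = which(!skipped),
                    label = epochLabels(epochs)[!skipped])
  for (si in seq_along(paramsList))
    for (ci in seq_len(nch))
      out[[sprintf("lle_%s_%s", channelNames(epochs)[ci],
                   names(paramsList)[si])]] <- feats[[si]][!skipped, ci]
  out
}

#' LLE feature table for an epoch set
#'
#' Computes [lleFeature()] for every epoch and channel, using per-class
#' embedding ceilings when `paramsByClass` is a named list ("open"/"fist");
#' a single `EmbeddingParams` applies to both classes. Epochs for which any
#' stage fails (for example an embedding ceiling infeasible at the epoch
#' length) are skipped; if more than `maxSkipFraction` of the epochs are
#' skipped an error is raised.
#'
#' @param epochs an [EpochSet-class].
#' @param paramsByClass an [embeddingParams()] or a named list of them.
#' @param dt seconds per sample; defaults to 1/fs of the epoch set.
#' @param maxSteps divergence steps to track.
#' @param maxSkipFraction largest tolerated fraction of skipped epochs.
#' @return data.frame with columns epoch, label, one feature column per
#'   channel (named `lle_<channel>`).
#' @export
lleFeatureMatrix <- function(epochs, paramsByClass = embeddingParams(),
                             dt = NULL, maxSteps = 30L,
                             maxSkipFraction = 0.2) {
  if (is.null(dt)) dt <- 1 / samplingRate(epochs)
  if (is(paramsByClass, "EmbeddingParams"))
    paramsByClass <- list(open = paramsByClass, fist = paramsByClass)
  labs <- epochLabels(epochs)
  dat <- epochData(epochs)
  nch <- nChannels(epochs)
  feat <- matrix(NA_real_, nEpochs(epochs), nch)
  for (ei in seq_len(nEpochs(epochs))) {
    par <- paramsByClass[[labs[ei]]]
    if (is.null(par)) par <- paramsByClass[[1L]]
    for (ci in seq_len(nch)) {
      feat[ei, ci] <- tryCatch(
        lleFeature(dat[ei, ci, ], par, dt = dt, maxSteps = maxSteps),
        error = function(e) NA_real_)
    }
  }
  skipped <- apply(feat, 1, function(r) any(!is.finite(r)))
  if (mean(skipped) > maxSkipFraction)
    stop(sprintf("%.0f%% of epochs failed feature extraction (limit %.0f%%)",
                 100 * mean(skipped), 100 * maxSkipFraction))
  out <- data.frame(epoch = which(!skipped), label = labs[!skipped])
  for (ci in seq_len(nch))
    out[[paste0("lle_", channelNames(epochs)[ci])]] <- feat[!skipped, ci]
  out
}
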