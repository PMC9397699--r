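#' @include lyapunov.R classify.R optimizers.R preprocess.R
NULL

#' RunReport: the outcome of one end-to-end pipeline run
#'
#' @slot method "traditional", "wd" or "ctw".
#' @slot meanAccuracy mean held-out test accuracy over the repeats.
#' @slot accuracies per-repeat accuracies.
#' @slot theta selected (maxLag_open, maxDim_open, maxLag_fist,
#'   maxDim_fist).
#' @slot screen per-channel paired t-test screen results.
#' @slot optimizerHistory best-so-far fitness trace (empty for
#'   traditional).
#' @slot develIdx,holdoutIdx epoch indices of the optimizer-visible and
#'   held-out partitions (leakage audit).
#' @slot config the configuration list used.
#' @exportClass RunReport
setClass("RunReport",
  representation(method = "character", meanAccuracy = "numeric",
                 accuracies = "numeric", theta = "numeric",
                 screen = "data.frame", optimizerHistory = "data.frame",
                 develIdx = "integer", holdoutIdx = "integer",
                 config = "list"),
  validity = function(object) {
    if (length(object@theta) != 4L) return("theta must have 4 entries")
    if (any(object@accuracies < 0 | object@accuracies > 1))
      return("accuracies must lie in [0, 1]")
    if (length(intersect(object@develIdx, object@holdoutIdx)) > 0L)
      return("devel and holdout partitions overlap")
    TRUE
  })

#' @export
setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport (%s): mean accuracy %.3f over %d repeats\n",
              object@method, object@meanAccuracy, length(object@accuracies)))
  cat(sprintf("  ceilings: open (lag<=%d, dim<=%d), fist (lag<=%d, dim<=%d)\n",
              object@theta[1], object@theta[2], object@theta[3],
              object@theta[4]))
})

#' Pipeline configuration
#'
#' @param method "traditional" (fixed ceilings lag <= 10, dim <= 3), "wd"
#'   (ceilings tuned by Intelligent Water Drop) or "ctw" (tuned by Chaotic
#'   Tug-of-War).
#' @param bandLow,bandHigh,filterOrder Butterworth bandpass settings.
#' @param channels channels used for features (NULL = all).
#' @param lagBounds,dimBounds search intervals for the per-class ceilings.
#' @param budget optimizer evaluation budget (cost-function calls).
#' @param fitness "fisher" (negative Fisher ratio of the class features;
#'   cheap surrogate) or "accuracy" (1 - k-fold CV accuracy).
#' @param surrogatePerClass epochs per class subsampled from the
#'   optimizer-visible partition for each fitness evaluation.
#' @param mapId chaotic map driving the ctw method.
#' @param C,tau,k SVM regularization, kernel shape, CV folds.
#' @param nRepeats number of random re-splits averaged into the reported
#'   accuracy.
#' @param seed master seed; every stage derives its stream from it.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(method = c("traditional", "wd", "ctw"),
                           bandLow = 8, bandHigh = 15, filterOrder = 6,
                           channels = NULL,
                           lagBounds = c(2L, 100L), dimBounds = c(2L, 60L),
                           budget = 10000L, fitness = c("fisher", "accuracy"),
                           surrogatePerClass = 24L, mapId = "logistic",
                           C = 1, tau = 2, k = 5L, nRepeats = 20L,
                           seed = 1L) {
  method <- match.arg(method)
  fitness <- match.arg(fitness)
  structure(list(method = method, bandLow = bandLow, bandHigh = bandHigh,
                 filterOrder = filterOrder, channels = channels,
                 lagBounds = as.integer(lagBounds),
                 dimBounds = as.integer(dimBounds),
                 budget = as.integer(budget), fitness = fitness,
                 surrogatePerClass = as.integer(surrogatePerClass),
                 mapId = mapId, C = C, tau = tau, k = as.integer(k),
                 nRepeats = as.integer(nRepeats), seed = as.integer(seed)),
            class = "PipelineConfig")
}

# Fisher discriminant ratio summed over feature columns.
fisherRatio <- function(features, labels) {
  cls <- unique(labels)
  a <- features[labels == cls[1], , drop = FALSE]
  b <- features[labels == cls[2], , drop = FALSE]
  num <- (colMeans(a) - colMeans(b))^2
  den <- apply(a, 2, var) + apply(b, 2, var)
  sum(num / pmax(den, 1e-12))
}

#' Cost of a four-parameter embedding-ceiling vector
#'
#' theta = (maxLag_open, maxDim_open, maxLag_fist, maxDim_fist), rounded to
#' integers: both per-class ceiling pairs are applied to every epoch as
#' label-free feature maps ([lleFeatureSets()]), and the cost is either 1
#' minus the stratified
#' k-fold SVM accuracy or the negative Fisher ratio of the features
#' (`fitness = "fisher"`). Smaller is better; this is the cost function the
#' metaheuristics minimize under the 10,000-evaluation budget.
#'
#' @param theta numeric length-4 vector of ceilings.
#' @param epochs an [EpochSet-class] (typically the optimizer-visible
#'   training partition, already band-filtered).
#' @param fitness "accuracy" or "fisher".
#' @param k,C,tau classifier settings for the accuracy fitness.
#' @param seed seed for the CV fold assignment.
#' @param lagBounds,dimBounds admissible ceiling ranges.
#' @return Scalar cost (may be `Inf` when feature extraction fails for more
#'   than 20% of the epochs).
#' @export
fitnessFromParams <- function(theta, epochs, fitness = c("fisher", "accuracy"),
                              k = 5L, C = 1, tau = 2, seed = NULL,
                              lagBounds = c(2L, 100L), dimBounds = c(2L, 60L)) {
  fitness <- match.arg(fitness)
  theta <- round(theta)
  if (length(theta) != 4L) stop("theta must have 4 entries")
  lags <- theta[c(1, 3)]; dims <- theta[c(2, 4)]
  if (any(dims < 2L)) stop("embedding dimension ceilings must be >= 2")
  if (any(lags < lagBounds[1] | lags > lagBounds[2]) ||
      any(dims > dimBounds[2]))
    stop("theta outside the admissible ceiling bounds")
  paramSets <- list(
    open = embeddingParams(maxLag = theta[1], maxDim = theta[2]),
    fist = embeddingParams(maxLag = theta[3], maxDim = theta[4]))
  feat <- lleFeatureSets(epochs, paramSets)
  X <- as.matrix(feat[, grep("^lle_", names(feat)), drop = FALSE])
  y <- feat$label
  if (length(unique(y)) < 2L) stop("a class lost all epochs during extraction")
  if (fitness == "fisher") return(-fisherRatio(X, y))
  sigma <- medianHeuristicSigma(X)
  1 - crossValidatedAccuracy(X, y, k = k, C = C,
                             params = grbfParams(sigma = sigma, tau = tau),
                             seed = seed)
}

# Stratified subsample of an epoch set (indices into the set).
subsampleEpochs <- function(labels, perClass, seed) {
  withSeed(seed, function() {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, min(perClass, length(idx)))
    }))
  })
}

epochSubset <- function(epochs, idx) {
  EpochSet(epochData(epochs)[idx, , , drop = FALSE], epochLabels(epochs)[idx],
           samplingRate(epochs), channelNames(epochs), epochs@window)
}

#' Run one end-to-end pipeline variant
#'
#' Band-pass filters the epochs, optionally tunes the per-class embedding
#' ceilings with the configured metaheuristic, extracts per-channel LLE
#' features, screens them with a paired t test (p < 0.05 advance; if none
#' does, the best-p channel is retained with a warning), and reports the
#' mean SVM test accuracy over `nRepeats` random splits.
#'
#' Leakage guard: the epoch set is split once (stratified, by the master
#' seed) into an optimizer-visible partition (70%) and a holdout (30%);
#' the optimizer cost function only ever sees the former, and every
#' reported test accuracy is measured on epochs drawn from the latter.
#'
#' @param config a [pipelineConfig()].
#' @param epochs a labeled [EpochSet-class] with both classes present.
#' @return A [RunReport-class].
#' @export
runOffline <- function(config, epochs) {
  stopifnot(inherits(config, "PipelineConfig"))
  labs <- epochLabels(epochs)
  if (length(unique(labs)) != 2L) stop("[input] both classes must be present")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  epochs <- stage("bandpass-filter",
                  bandpassFilter(epochs, config$bandLow, config$bandHigh,
                                 config$filterOrder))
  if (!is.null(config$channels))
    epochs <- stage("channel-selection", selectChannels(epochs, config$channels))

  # devel / holdout partition (stratified 70/30)
  part <- withSeed(config$seed, function() {
    unlist(lapply(unique(labs), function(cl) {
      idx <- sample(which(labs == cl))
      utils::head(idx, round(0.7 * length(idx)))
    }))
  })
  develIdx <- sort(part)
  holdoutIdx <- setdiff(seq_along(labs), develIdx)

  traditionalTheta <- c(10, 3, 10, 3)
  history <- data.frame(eval = integer(0), best = numeric(0))
  if (config$method == "traditional") {
    theta <- traditionalTheta
  } else {
    devel <- epochSubset(epochs, develIdx)
    sub <- subsampleEpochs(epochLabels(devel), config$surrogatePerClass,
                           seed = config$seed + 1L)
    surrogate <- epochSubset(devel, sub)
    # features on the fixed surrogate depend on theta only through the
    # 2-D (maxLag, maxDim) cell of each parameter set; cache per cell so
    # revisits by the population cost nothing (every call still counts
    # against the evaluation budget)
    setCache <- new.env(parent = emptyenv())
    setFeatures <- function(lagC, dimC) {
      key <- paste(lagC, dimC)
      if (!is.null(setCache[[key]])) return(setCache[[key]])
      f <- tryCatch(
        lleFeatureSets(surrogate,
                       list(s = embeddingParams(maxLag = lagC, maxDim = dimC)),
                       maxSkipFraction = 1),
        error = function(e) NULL)
      out <- if (is.null(f)) NULL else {
        full <- matrix(NA_real_, nEpochs(surrogate), nChannels(surrogate))
        full[f$epoch, ] <- as.matrix(f[, grep("^lle_", names(f)),
                                       drop = FALSE])
        full
      }
      setCache[[key]] <- out
      out
    }
    surLabels <- epochLabels(surrogate)
    cost <- function(th) {
      th <- round(th)
      if (any(th[c(1, 3)] < config$lagBounds[1]) ||
          any(th[c(1, 3)] > config$lagBounds[2]) ||
          any(th[c(2, 4)] < config$dimBounds[1]) ||
          any(th[c(2, 4)] > config$dimBounds[2])) return(Inf)
      F1 <- setFeatures(th[1], th[2]); F2 <- setFeatures(th[3], th[4])
      if (is.null(F1) || is.null(F2)) return(Inf)
      X <- cbind(F1, F2)
      ok <- rowSums(!is.finite(X)) == 0L
      if (mean(ok) < 0.8 || length(unique(surLabels[ok])) < 2L) return(Inf)
      X <- X[ok, , drop = FALSE]
      if (config$fitness == "fisher") return(-fisherRatio(X, surLabels[ok]))
      tryCatch(
        1 - crossValidatedAccuracy(X, surLabels[ok], k = config$k,
              C = config$C,
              params = grbfParams(sigma = medianHeuristicSigma(X),
                                  tau = config$tau),
              seed = config$seed + 2L),
        error = function(e) Inf)
    }
    lb <- c(config$lagBounds[1], config$dimBounds[1])
    ub <- c(config$lagBounds[2], config$dimBounds[2])
    space <- searchSpace(rep(lb, 2), rep(ub, 2),
                         integerMask = rep(TRUE, 4))
    res <- stage("optimizer", if (config$method == "ctw") {
      runOptimizer(cost, space, method = "ctw",
                   config = twConfig(seed = config$seed + 3L,
                                     maxEvaluations = config$budget,
                                     alpha = 0.98, mapId = config$mapId))
    } else {
      runOptimizer(cost, space, method = "iwd",
                   config = iwdConfig(seed = config$seed + 3L,
                                      maxEvaluations = config$budget))
    })
    theta <- round(res@bestX)
    history <- res@history
    if (!all(is.finite(theta)) || res@bestF == Inf) {
      theta <- traditionalTheta
    } else if (cost(traditionalTheta) < res@bestF) {
      # the tuned ceilings must at least beat the traditional setting on
      # the optimizer's own objective; otherwise keep the default
      theta <- traditionalTheta
    }
  }

  paramSets <- list(
    open = embeddingParams(maxLag = theta[1], maxDim = theta[2]),
    fist = embeddingParams(maxLag = theta[3], maxDim = theta[4]))
  feat <- stage("feature-extraction", lleFeatureSets(epochs, paramSets))
  featCols <- grep("^lle_", names(feat), value = TRUE)

  # paired t-test screen: features of class pairs matched by within-class
  # rank (no subject structure in pooled epochs)
  screen <- do.call(rbind, lapply(featCols, function(cn) {
    a <- feat[[cn]][feat$label == "open"]
    b <- feat[[cn]][feat$label == "fist"]
    m <- min(length(a), length(b))
    res <- tryCatch(pairedFeatureTTest(a[seq_len(m)], b[seq_len(m)]),
                    error = function(e) list(statistic = NA_real_,
                                             p.value = NA_real_))
    data.frame(feature = cn, statistic = res$statistic, p = res$p.value)
  }))
  keep <- screen$feature[!is.na(screen$p) & screen$p < 0.05]
  if (length(keep) == 0L) {
    keep <- screen$feature[which.min(screen$p)]
    if (length(keep) == 0L) keep <- featCols
    warning("no feature passed the paired t-test screen; keeping best-p feature")
  }

  X <- as.matrix(feat[, keep, drop = FALSE])
  y <- feat$label
  rowsDevel <- which(feat$epoch %in% develIdx)
  rowsHold <- which(feat$epoch %in% holdoutIdx)
  # each repeat retrains on a fresh stratified 80% of the optimizer-visible
  # partition and scores the whole holdout, so the average integrates out
  # training noise while the holdout stays optimizer-unseen
  accs <- withSeed(config$seed + 4L, function() {
    vapply(seq_len(config$nRepeats), function(r) {
      tr <- unlist(lapply(unique(y[rowsDevel]), function(cl) {
        idx <- rowsDevel[y[rowsDevel] == cl]
        sample(idx, max(2L, round(0.8 * length(idx))))
      }))
      sigma <- medianHeuristicSigma(X[tr, , drop = FALSE])
      model <- trainSMSVM(X[tr, , drop = FALSE], y[tr], C = config$C,
                          params = grbfParams(sigma = sigma, tau = config$tau))
      mean(predictSMSVM(model, X[rowsHold, , drop = FALSE]) == y[rowsHold])
    }, numeric(1))
  })

  new("RunReport", method = config$method, meanAccuracy = mean(accs),
      accuracies = accs, theta = as.numeric(theta), screen = screen,
      optimizerHistory = history, develIdx = as.integer(develIdx),
      holdoutIdx = as.integer(holdoutIdx), config = unclass(config))
}

#' Tabulate pipeline reports side by side
#'
#' @param reports list of [RunReport-class] objects (>= 1, with accuracies).
#' @return data.frame with one column per method and rows: max selected
#'   lag, max selected dimension, offline average accuracy.
#' @export
reportTable <- function(reports) {
  if (length(reports) == 0L) stop("need at least one report")
  for (r in reports) if (length(r@accuracies) == 0L)
    stop("report with empty accuracy list")
  out <- data.frame(row.names = c("Max selected lag",
                                  "Max selected dimension",
                                  "Offline average accuracy"))
  for (r in reports) {
    out[[r@method]] <- c(max(r@theta[c(1, 3)]), max(r@theta[c(2, 4)]),
                         round(r@meanAccuracy, 4))
  }
  out
}

#' Write a run report as JSON (plus a CSV accuracy table)
#'
#' @param report a [RunReport-class].
#' @param path output JSON path; the per-repeat accuracies go to
#'   `<path>.csv`.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(
    list(method = report@method, mean_accuracy = report@meanAccuracy,
         accuracies = report@accuracies, theta = report@theta,
         screen = report@screen, config = report@config),
    path, auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(method = report@method,
                       repeat_ = seq_along(report@accuracies),
                       accuracy = report@accuracies),
            paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
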