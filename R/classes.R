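#' @include chaolle-package.R
NULL

#' EpochSet: labeled fixed-length multichannel EEG segments
#'
#' Container for a collection of equally long epochs cut around task cues.
#' The data cube is epochs x channels x samples; each epoch carries a binary
#' class label ("open" or "fist" in the motor-imagery task).
#'
#' @slot data numeric array, epochs x channels x samples.
#' @slot labels character vector, one label per epoch (two classes at most).
#' @slot fs sampling rate in Hz.
#' @slot channelNames channel names, length = dim(data)[2].
#' @slot window numeric length-2, (pre, post) extent of the epoch in ms
#'   relative to the cue.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", labels = "character", fs = "numeric",
                 channelNames = "character", window = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-D array (epochs x channels x samples)")
    if (length(object@labels) != d[1L]) return("one label per epoch required")
    if (length(object@channelNames) != d[2L]) return("one name per channel required")
    if (length(unique(object@labels)) > 2L) return("at most two classes supported")
    if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a positive scalar")
    if (length(object@window) != 2L) return("window must be (pre_ms, post_ms)")
    if (d[1L] > 0 && !all(is.finite(object@data))) return("non-finite values in data")
    TRUE
  })

#' Construct an EpochSet
#'
#' @param data epochs x channels x samples array.
#' @param labels per-epoch class labels.
#' @param fs sampling rate (Hz).
#' @param channelNames channel names.
#' @param window (pre_ms, post_ms) epoch extent relative to the cue.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(data, labels, fs, channelNames, window = c(200, 2500)) {
  new("EpochSet", data = data, labels = as.character(labels), fs = fs,
      channelNames = channelNames, window = as.numeric(window))
}

#' @describeIn EpochSet number of epochs
#' @param x,object an EpochSet
#' @export
nEpochs <- function(x) dim(x@data)[1L]

#' @describeIn EpochSet number of channels
#' @export
nChannels <- function(x) dim(x@data)[2L]

#' @describeIn EpochSet samples per epoch
#' @export
nSamples <- function(x) dim(x@data)[3L]

#' @describeIn EpochSet the epochs x channels x samples data cube
#' @export
epochData <- function(x) x@data

#' @describeIn EpochSet per-epoch labels
#' @export
epochLabels <- function(x) x@labels

#' @describeIn EpochSet sampling rate in Hz
#' @export
samplingRate <- function(x) x@fs

#' @describeIn EpochSet channel names
#' @export
channelNames <- function(x) x@channelNames

#' @export
setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  if (d[1] > 0) {
    tb <- table(object@labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  cat(sprintf("  window: -%g..+%g ms around cue\n", object@window[1], object@window[2]))
})

#' ContinuousRecording: a continuous multichannel recording with event markers
#'
#' @slot data channels x samples matrix (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channelNames channel names, length = nrow(data).
#' @slot markers data.frame with columns `sample` (0-based cue sample index)
#'   and `label` (class label).
#' @exportClass ContinuousRecording
setClass("ContinuousRecording",
  representation(data = "matrix", fs = "numeric", channelNames = "character",
                 markers = "data.frame"),
  validity = function(object) {
    if (nrow(object@data) != length(object@channelNames))
      return("one name per channel (row) required")
    if (!all(c("sample", "label") %in% names(object@markers)))
      return("markers need columns `sample` and `label`")
    if (nrow(object@markers) > 0 &&
        (any(object@markers$sample < 0) ||
         any(object@markers$sample >= ncol(object@data))))
      return("marker sample indices must lie within the recording")
    TRUE
  })

#' Construct a ContinuousRecording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param channelNames channel names.
#' @param markers data.frame with columns `sample` (0-based) and `label`.
#' @return A [ContinuousRecording-class] object.
#' @export
ContinuousRecording <- function(data, fs, channelNames, markers) {
  new("ContinuousRecording", data = data, fs = fs,
      channelNames = channelNames, markers = markers)
}

#' @export
setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording: %d channels x %d samples @ %g Hz, %d markers\n",
              nrow(object@data), ncol(object@data), object@fs, nrow(object@markers)))
})

#' EmbeddingParams: delay-embedding parameters and their search ceilings
#'
#' Houses the time lag (selected at the first local minimum of the mutual
#' information curve), the embedding dimension (selected by the false-nearest
#' -neighbor criterion), the ceilings bounding both searches, and the FNN
#' tuning constants.
#'
#' @slot lag selected time lag in samples (NA until selected).
#' @slot dim selected embedding dimension (NA until selected).
#' @slot maxLag ceiling for the lag search (>= 2).
#' @slot maxDim ceiling for the dimension search (>= 2).
#' @slot nBins histogram bins for the mutual-information estimate.
#' @slot fnnRtol relative-distance false-neighbor threshold.
#' @slot fnnAtol attractor-size false-neighbor threshold.
#' @slot fnnFracThreshold acceptable false-neighbor fraction.
#' @exportClass EmbeddingParams
setClass("EmbeddingParams",
  representation(lag = "integer", dim = "integer", maxLag = "integer",
                 maxDim = "integer", nBins = "integer", fnnRtol = "numeric",
                 fnnAtol = "numeric", fnnFracThreshold = "numeric"),
  validity = function(object) {
    if (object@maxLag < 2L) return("maxLag must be >= 2")
    if (object@maxDim < 2L) return("maxDim must be >= 2")
    if (!is.na(object@lag) && (object@lag < 1L || object@lag > object@maxLag))
      return("lag must satisfy 1 <= lag <= maxLag")
    if (!is.na(object@dim) && (object@dim < 2L || object@dim > object@maxDim))
      return("dim must satisfy 2 <= dim <= maxDim")
    if (object@nBins < 2L) return("nBins must be >= 2")
    TRUE
  })

#' Construct EmbeddingParams
#'
#' @param maxLag lag-search ceiling (samples). The traditional setting is 10.
#' @param maxDim dimension-search ceiling. The traditional setting is 3.
#' @param lag,dim preselected values (optional; NA = select from data).
#' @param nBins mutual-information histogram bins.
#' @param fnnRtol,fnnAtol,fnnFracThreshold false-nearest-neighbor thresholds.
#' @return An [EmbeddingParams-class] object.
#' @export
embeddingParams <- function(maxLag = 10L, maxDim = 3L, lag = NA_integer_,
                            dim = NA_integer_, nBins = 16L, fnnRtol = 15,
                            fnnAtol = 2, fnnFracThreshold = 0.01) {
  new("EmbeddingParams", lag = as.integer(lag), dim = as.integer(dim),
      maxLag = as.integer(maxLag), maxDim = as.integer(maxDim),
      nBins = as.integer(nBins), fnnRtol = fnnRtol, fnnAtol = fnnAtol,
      fnnFracThreshold = fnnFracThreshold)
}

#' @export
setMethod("show", "EmbeddingParams", function(object) {
  cat(sprintf("EmbeddingParams: lag=%s (max %d), dim=%s (max %d)\n",
              ifelse(is.na(object@lag), "?", object@lag), object@maxLag,
              ifelse(is.na(object@dim), "?", object@dim), object@maxDim))
})

#' Trajectory: delay-embedded phase-space points
#'
#' Rows are phase-space points `[x_s, x_{s+lag}, ..., x_{s+(dim-1)lag}]`
#' reconstructed from a scalar series (Takens embedding).
#'
#' @slot points (N - (dim-1)*lag) x dim matrix of phase-space points.
#' @slot sourceLength length N of the originating series.
#' @slot lag embedding lag (samples).
#' @slot dim embedding dimension.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(points = "matrix", sourceLength = "integer",
                 lag = "integer", dim = "integer"),
  validity = function(object) {
    expected <- object@sourceLength - (object@dim - 1L) * object@lag
    if (nrow(object@points) != expected)
      return(sprintf("row count %d != N - (dim-1)*lag = %d",
                     nrow(object@points), expected))
    if (ncol(object@points) != object@dim) return("ncol(points) must equal dim")
    TRUE
  })

#' @describeIn Trajectory phase-space point matrix
#' @param x a Trajectory
#' @export
trajectoryPoints <- function(x) x@points

#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d points in dimension %d (lag %d, source N=%d)\n",
              nrow(object@points), object@dim, object@lag, object@sourceLength))
})

#' DivergenceCurve: mean log-distance between neighbor pairs per step
#'
#' For each trajectory point paired with its nearest (Theiler-excluded)
#' neighbor, the Euclidean separation is tracked for i = 0..maxSteps; the
#' curve stores the mean of log separations per step. Its initial slope,
#' divided by the sample period, estimates the largest Lyapunov exponent.
#'
#' @slot steps integer step offsets i (starting at 0).
#' @slot meanLogDist mean over pairs of ln separation at each step.
#' @slot meanDist arithmetic mean separation per step (saturation detection).
#' @slot nPairs number of pairs contributing at each step.
#' @slot dt seconds per sample (1 for unit-free map time).
#' @slot extent attractor extent (max coordinate range), used for
#'   saturation detection when fitting.
#' @exportClass DivergenceCurve
setClass("DivergenceCurve",
  representation(steps = "integer", meanLogDist = "numeric",
                 meanDist = "numeric", nPairs = "integer", dt = "numeric",
                 extent = "numeric"),
  validity = function(object) {
    n <- length(object@steps)
    if (length(object@meanLogDist) != n || length(object@nPairs) != n)
      return("steps, meanLogDist and nPairs must have equal length")
    if (any(object@nPairs <= 0L)) return("every reported step needs > 0 pairs")
    if (!all(is.finite(object@meanLogDist))) return("meanLogDist must be finite")
    TRUE
  })

#' @export
setMethod("show", "DivergenceCurve", function(object) {
  cat(sprintf("DivergenceCurve: %d steps, %d pairs at step 0, dt=%g\n",
              length(object@steps), object@nPairs[1], object@dt))
})

#' LLEResult: a largest-Lyapunov-exponent estimate with its fit diagnostics
#'
#' @slot lle the exponent in nats per second (nats per iteration when dt = 1).
#' @slot fitRange (first, last) step of the linear fit on the divergence curve.
#' @slot r2 coefficient of determination of the fit.
#' @slot curve the underlying [DivergenceCurve-class].
#' @exportClass LLEResult
setClass("LLEResult",
  representation(lle = "numeric", fitRange = "integer", r2 = "numeric",
                 curve = "DivergenceCurve"),
  validity = function(object) {
    if (length(object@fitRange) != 2L) return("fitRange must be (start, end)")
    if (object@fitRange[1] < min(object@curve@steps) ||
        object@fitRange[2] > max(object@curve@steps))
      return("fitRange outside the divergence curve")
    if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
      return("r2 must lie in [0, 1]")
    TRUE
  })

#' @describeIn LLEResult the scalar exponent estimate
#' @param x an LLEResult
#' @export
lleValue <- function(x) x@lle

#' @export
setMethod("show", "LLEResult", function(object) {
  cat(sprintf("LLEResult: lle = %.4f (fit over steps %d..%d, r2 = %.3f)\n",
              object@lle, object@fitRange[1], object@fitRange[2], object@r2))
})

#' GRBFParams: generalized radial basis function kernel parameters
#'
#' K(x, z) = exp(-||x - z||^tau / (2 sigma^tau)). tau = 2 recovers the
#' standard Gaussian RBF with bandwidth sigma; tau is restricted to (0, 2]
#' so the kernel stays positive definite. The center parameter translates
#' the feature space before kernel evaluation.
#'
#' @slot sigma kernel width (> 0).
#' @slot tau shape exponent in (0, 2].
#' @slot center feature-space translation (recycled to feature length).
#' @exportClass GRBFParams
setClass("GRBFParams",
  representation(sigma = "numeric", tau = "numeric", center = "numeric"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@tau <= 0 || object@tau > 2)
      return("tau must lie in (0, 2] (kernel validity)")
    TRUE
  })

#' Construct GRBFParams
#'
#' @param sigma kernel width, > 0.
#' @param tau shape exponent in (0, 2]; 2 gives the standard RBF.
#' @param center feature-space center (default 0).
#' @return A [GRBFParams-class] object.
#' @export
grbfParams <- function(sigma = 1, tau = 2, center = 0) {
  new("GRBFParams", sigma = sigma, tau = tau, center = as.numeric(center))
}

#' @export
setMethod("show", "GRBFParams", function(object) {
  cat(sprintf("GRBFParams: sigma=%g, tau=%g, center=(%s)\n", object@sigma,
              object@tau, paste(signif(object@center, 3), collapse = ", ")))
})

#' SMSVMModel: a trained soft-margin SVM with generalized-RBF kernel
#'
#' @slot svm the fitted kernlab model (on the precomputed Gram matrix).
#' @slot trainFeatures training feature matrix (needed for test kernels).
#' @slot levels the two class labels, negative level first.
#' @slot cost soft-margin regularization constant C.
#' @slot params the [GRBFParams-class] used.
#' @exportClass SMSVMModel
setClass("SMSVMModel",
  representation(svm = "ANY", trainFeatures = "matrix", levels = "character",
                 cost = "numeric", params = "GRBFParams"),
  validity = function(object) {
    if (length(object@levels) != 2L) return("binary classifier requires 2 levels")
    if (object@cost <= 0) return("C must be > 0")
    TRUE
  })

#' @export
setMethod("show", "SMSVMModel", function(object) {
  cat(sprintf("SMSVMModel: %d training points, C=%g, sigma=%g, tau=%g\n",
              nrow(object@trainFeatures), object@cost, object@params@sigma,
              object@params@tau))
  cat("  classes:", paste(object@levels, collapse = " vs "), "\n")
})

#' OptimizationResult: outcome of a budgeted metaheuristic run
#'
#' @slot bestX best decision vector found.
#' @slot bestF its fitness (minimization convention).
#' @slot evaluations number of cost-function evaluations spent.
#' @slot history data.frame (eval, best) of best-so-far fitness.
#' @slot method optimizer name.
#' @exportClass OptimizationResult
setClass("OptimizationResult",
  representation(bestX = "numeric", bestF = "numeric", evaluations = "integer",
                 history = "data.frame", method = "character"))

#' @export
setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf("OptimizationResult (%s): best F = %.6g after %d evaluations\n",
              object@method, object@bestF, object@evaluations))
  cat("  best X:", paste(signif(object@bestX, 5), collapse = ", "), "\n")
})
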