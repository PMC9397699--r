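#' @include classes.R
NULL

# Butterworth bandpass designed directly in zero-pole form and realized as
# second-order sections. The transfer-function (b, a) form of a 6th-order
# bandpass with edges far below Nyquist is numerically unstable (poles leave
# the unit circle through coefficient rounding), so sections are mandatory.
butterBandpassSos <- function(order, low, high, fs) {
  if (fs <= 2 * high)
    stop(sprintf("fs = %g Hz must exceed twice the high edge (%g Hz)", fs, high))
  n <- order
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # analog prototype poles
  w1 <- tan(pi * low / fs); w2 <- tan(pi * high / fs)  # prewarped edges
  w0 <- sqrt(w1 * w2); B <- w2 - w1
  poles <- unlist(lapply(pa, function(p) {
    d <- sqrt((p * B / 2)^2 - w0^2)
    c(p * B / 2 + d, p * B / 2 - d)
  }))
  zp <- (1 + poles) / (1 - poles)                  # bilinear transform
  if (any(Mod(zp) >= 1))
    stop("unstable filter design for this sampling rate; ",
         "use wider band edges or a lower order")
  ph <- zp[Im(zp) > 0]
  sos <- lapply(ph, function(p)
    list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2)))
  wc <- 2 * atan(w0)
  z1 <- exp(-1i * wc)
  H <- 1 + 0i
  for (s in sos) H <- H * sum(s$b * z1^(0:2)) / sum(s$a * z1^(0:2))
  list(sos = sos, gain = 1 / Mod(H), fs = fs, low = low, high = high)
}

# Zero-phase application of the section cascade: the signal is extended by
# odd reflection at both ends, and the squared magnitude response — exactly
# the forward-backward (filtfilt) response — is applied in the frequency
# domain. This sidesteps the long start-up transients an IIR realization of
# this narrow band would have.
sosZeroPhase <- function(filt, x) {
  n <- length(x)
  if (n < 3L) stop("signal too short to filter")
  p <- n - 1L
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  m <- length(xp)
  nfft <- 2^ceiling(log2(m))
  xp <- c(xp, numeric(nfft - m))
  z1 <- exp(-1i * 2 * pi * (0:(nfft - 1)) / nfft)
  H <- rep(1 + 0i, nfft)
  for (s in filt$sos)
    H <- H * (s$b[1] + s$b[2] * z1 + s$b[3] * z1^2) /
             (s$a[1] + s$a[2] * z1 + s$a[3] * z1^2)
  H2 <- (Mod(H) * filt$gain)^2
  y <- Re(fft(fft(xp) * H2, inverse = TRUE)) / nfft
  y[(p + 1):(p + n)]
}

#' Cut a continuous recording into labeled epochs around its markers
#'
#' One epoch per marker, covering the half-open window
#' `[cue - pre, cue + post)` in 0-based sample indices, i.e.
#' `round((preMs + postMs) * fs / 1000)` samples starting
#' `round(preMs * fs / 1000)` samples before the cue.
#'
#' @param rec a [ContinuousRecording-class].
#' @param preMs window start before the cue (ms), default 200.
#' @param postMs window end after the cue (ms), default 2500.
#' @return An [EpochSet-class]; zero markers yield an empty set.
#' @export
segmentTrials <- function(rec, preMs = 200, postMs = 2500) {
  fs <- rec@fs
  len <- round((preMs + postMs) * fs / 1000)
  pre <- round(preMs * fs / 1000)
  mk <- rec@markers
  nch <- nrow(rec@data)
  if (nrow(mk) == 0L)
    return(EpochSet(array(0, c(0L, nch, len)), character(0), fs,
                    rec@channelNames, c(preMs, postMs)))
  starts <- mk$sample - pre                  # 0-based epoch starts
  bad <- starts < 0 | starts + len > ncol(rec@data)
  if (any(bad))
    stop("markers too close to the recording edge at samples: ",
         paste(mk$sample[bad], collapse = ", "))
  data <- array(0, c(nrow(mk), nch, len))
  for (ei in seq_len(nrow(mk)))
    data[ei, , ] <- rec@data[, (starts[ei] + 1):(starts[ei] + len), drop = FALSE]
  EpochSet(data, mk$label, fs, rec@channelNames, c(preMs, postMs))
}

#' Band-pass filter every epoch with a zero-phase Butterworth filter
#'
#' Applies an order-`order` Butterworth bandpass (default 8-15 Hz, the
#' mu/alpha range carrying ERD/ERS) forward-backward (zero phase, effective
#' order 2 x `order`) to each epoch and channel. The filter is realized as
#' second-order sections for numerical stability.
#'
#' @param epochs an [EpochSet-class].
#' @param low,high band edges in Hz.
#' @param order Butterworth order (default 6).
#' @return A filtered [EpochSet-class] of identical shape.
#' @export
bandpassFilter <- function(epochs, low = 8, high = 15, order = 6) {
  filt <- butterBandpassSos(order, low, high, samplingRate(epochs))
  dat <- epochData(epochs)
  for (ei in seq_len(nEpochs(epochs)))
    for (ci in seq_len(nChannels(epochs)))
      dat[ei, ci, ] <- sosZeroPhase(filt, dat[ei, ci, ])
  EpochSet(dat, epochLabels(epochs), samplingRate(epochs),
           channelNames(epochs), epochs@window)
}

#' Subset and reorder the channels of an epoch set
#'
#' @param epochs an [EpochSet-class].
#' @param names channels to keep, in the requested order. The motor-imagery
#'   pipeline uses C3 and CP5.
#' @return An [EpochSet-class] with the selected channels.
#' @export
selectChannels <- function(epochs, names = c("C3", "CP5")) {
  idx <- match(names, channelNames(epochs))
  if (anyNA(idx))
    stop("unknown channel(s) ", paste(names[is.na(idx)], collapse = ", "),
         "; available: ", paste(channelNames(epochs), collapse = ", "))
  EpochSet(epochData(epochs)[, idx, , drop = FALSE], epochLabels(epochs),
           samplingRate(epochs), names, epochs@window)
}

#' Read a continuous recording from a delimited text matrix + JSON sidecar
#'
#' The data file holds one sample per row and one channel per column
#' (header optional); the sidecar is JSON with fields `fs`, `channel_names`
#' and `markers` (array of objects with `sample`, 0-based, and `label`).
#'
#' @param dataFile path to the delimited numeric matrix.
#' @param sidecarFile path to the JSON sidecar; defaults to
#'   `<dataFile>.json`.
#' @param sep field separator of the data file.
#' @return A [ContinuousRecording-class].
#' @export
readRecordingTxt <- function(dataFile, sidecarFile = paste0(dataFile, ".json"),
                             sep = ",") {
  meta <- jsonlite::fromJSON(sidecarFile)
  mat <- as.matrix(read.csv(dataFile, sep = sep, header = FALSE,
                            comment.char = "#"))
  if (!is.numeric(mat[1, 1])) {  # header present: reread
    mat <- as.matrix(read.csv(dataFile, sep = sep, header = TRUE))
  }
  storage.mode(mat) <- "double"
  markers <- as.data.frame(meta$markers)
  ContinuousRecording(t(mat), meta$fs, as.character(meta$channel_names),
                      markers)
}

#' Write an epoch set as a long-format CSV plus JSON metadata
#'
#' The CSV columns are epoch (1-based), channel, sample (0-based) and value;
#' the JSON sidecar stores labels, fs, channel names and the epoch window.
#'
#' @param epochs an [EpochSet-class].
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeEpochSet <- function(epochs, path) {
  dat <- epochData(epochs)
  d <- dim(dat)
  df <- data.frame(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(channelNames(epochs), each = d[1]), times = d[3]),
    sample = rep(0:(d[3] - 1), each = d[1] * d[2]),
    value = as.vector(dat))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = samplingRate(epochs), labels = epochLabels(epochs),
         channel_names = channelNames(epochs),
         window = epochs@window),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch set written by [writeEpochSet()]
#'
#' @param path CSV path (metadata expected at `<path>.json`).
#' @return An [EpochSet-class].
#' @export
readEpochSet <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  df <- read.csv(path)
  chans <- as.character(meta$channel_names)
  nE <- max(df$epoch); nC <- length(chans); nS <- max(df$sample) + 1L
  dat <- array(0, c(nE, nC, nS))
  ci <- match(df$channel, chans)
  dat[cbind(df$epoch, ci, df$sample + 1L)] <- df$value
  EpochSet(dat, as.character(meta$labels), meta$fs, chans,
           as.numeric(meta$window))
}
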