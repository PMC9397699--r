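makeRecording <- function(fs, nSamples, nCh = 2, markers) {
  set.seed(1)
  ContinuousRecording(matrix(rnorm(nCh * nSamples), nCh, nSamples), fs,
                      paste0("ch", seq_len(nCh)), markers)
}

test_that("segmentation cuts the half-open window around each marker", {
  rec <- makeRecording(1000, 9000,
                       markers = data.frame(sample = 5000, label = "open"))
  ep <- segmentTrials(rec, 200, 2500)
  expect_equal(nSamples(ep), 2700)
  # 0-based samples [4800, 7500) = R columns 4801..7500
  expect_identical(epochData(ep)[1, , ], rec@data[, 4801:7500])
  expect_equal(epochLabels(ep), "open")
})

test_that("epoch length follows round((pre+post)*fs/1000)", {
  rec <- makeRecording(512, 5000,
                       markers = data.frame(sample = 2000, label = "fist"))
  expect_equal(nSamples(segmentTrials(rec, 200, 2500)), 1382)
})

test_that("zero markers give an empty epoch set; edge markers error", {
  recEmpty <- makeRecording(256, 2000,
                            markers = data.frame(sample = integer(0),
                                                 label = character(0)))
  expect_equal(nEpochs(segmentTrials(recEmpty)), 0)

  recBad <- makeRecording(256, 800,
                          markers = data.frame(sample = c(100, 400),
                                               label = c("open", "fist")))
  expect_error(segmentTrials(recBad), "400")   # only 400 overruns the end
})

test_that("epoch count and labels map bijectively from markers", {
  mk <- data.frame(sample = c(1000, 2000, 3000),
                   label = c("open", "fist", "open"))
  ep <- segmentTrials(makeRecording(256, 4500, markers = mk), 200, 1000)
  expect_equal(nEpochs(ep), 3)
  expect_equal(epochLabels(ep), mk$label)
})

test_that("bandpass keeps the passband and kills the stopband", {
  fs <- 500
  t <- 0:1350   # ends on zero crossings of both tones
  mk <- function(freq) {
    EpochSet(array(sin(2 * pi * freq * t / fs), c(1, 1, length(t))),
             "open", fs, "C3")
  }
  inband <- bandpassFilter(mk(10))
  expect_gte(sqrt(mean(epochData(inband)^2)) / sqrt(mean(sin(2 * pi * 10 * t / fs)^2)),
             0.9)
  stop50 <- bandpassFilter(mk(50))
  expect_lte(sqrt(mean(epochData(stop50)^2)) / sqrt(0.5), 0.01)
  stop5 <- bandpassFilter(mk(5))
  expect_lte(sqrt(mean(epochData(stop5)^2)) / sqrt(0.5), 0.01)
})

test_that("filtering zeros returns zeros and preserves shape", {
  ep <- EpochSet(array(0, c(2, 2, 700)), c("open", "fist"), 256,
                 c("C3", "CP5"))
  out <- bandpassFilter(ep)
  expect_identical(dim(epochData(out)), dim(epochData(ep)))
  expect_true(all(epochData(out) == 0))
})

test_that("filter design rejects an inadequate sampling rate", {
  ep <- EpochSet(array(rnorm(200), c(1, 1, 200)), "open", 25, "C3")
  expect_error(bandpassFilter(ep), "exceed")
})

test_that("segment-then-filter matches filter-then-segment away from edges", {
  fs <- 256
  n <- 6000
  set.seed(4)
  sig <- as.numeric(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 1))
  sig[is.na(sig)] <- 0
  rec <- ContinuousRecording(matrix(sig, 1, n), fs, "C3",
                             data.frame(sample = 3000, label = "open"))
  a <- bandpassFilter(segmentTrials(rec, 200, 2500))
  filtRec <- rec
  filtRec@data[1, ] <- chaolle:::sosZeroPhase(
    chaolle:::butterBandpassSos(6, 8, 15, fs), sig)
  b <- segmentTrials(filtRec, 200, 2500)
  xa <- epochData(a)[1, 1, ]; xb <- epochData(b)[1, 1, ]
  # the narrowband filter rings over ~2/bandwidth s, so the epoch-level
  # reflection boundary is felt well into the segment; the two routes agree
  # closely only once that margin is trimmed
  core <- seq(round(length(xa) * 0.15), round(length(xa) * 0.85))
  expect_lt(sqrt(mean((xa[core] - xb[core])^2)) / sqrt(mean(xb[core]^2)), 0.05)
})

test_that("channel selection honors order and reports unknown names", {
  ep <- EpochSet(array(rnorm(3 * 3 * 50), c(3, 3, 50)),
                 c("open", "fist", "open"), 128, c("C3", "CP5", "Cz"))
  one <- selectChannels(ep, "C3")
  expect_equal(channelNames(one), "C3")
  expect_equal(nChannels(one), 1)
  rev2 <- selectChannels(ep, c("CP5", "C3"))
  expect_equal(channelNames(rev2), c("CP5", "C3"))
  expect_identical(epochData(rev2)[, 1, ], epochData(ep)[, 2, ])
  expect_error(selectChannels(ep, "C4"), "C4")
})

test_that("text recording reader and epoch container round-trip", {
  dir <- withr::local_tempdir()
  dataFile <- file.path(dir, "rec.csv")
  mat <- matrix(round(rnorm(400), 6), 200, 2)   # samples x channels
  write.table(mat, dataFile, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = 100, channel_names = c("C3", "CP5"),
                            markers = list(list(sample = 50, label = "open"))),
                       paste0(dataFile, ".json"), auto_unbox = TRUE)
  rec <- readRecordingTxt(dataFile)
  expect_equal(dim(rec@data), c(2, 200))
  expect_equal(rec@markers$label, "open")
  ep <- segmentTrials(rec, 100, 500)
  path <- file.path(dir, "epochs.csv")
  writeEpochSet(ep, path)
  back <- readEpochSet(path)
  expect_equal(epochData(back), epochData(ep), tolerance = 1e-12)
  expect_equal(epochLabels(back), epochLabels(ep))
  expect_equal(samplingRate(back), samplingRate(ep))
})
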