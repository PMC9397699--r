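# Shared fixtures, generated once per test run.

logisticSeries <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateSeries(chaoticSystemSpec("logistic", list(r = 4), 0.2,
                                                 nSamples = 5100,
                                                 transientDiscard = 100))
    cache
  }
})

henonSeries <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateSeries(chaoticSystemSpec("henon", nSamples = 5100,
                                                 transientDiscard = 100))
    cache
  }
})

# Small planted-effect epoch set (single channel keeps unit tests fast).
plantedEpochs <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- bandpassFilter(generateErdEpochs(erdConfig(
        nEpochsPerClass = 60, fs = 128, channels = "C3", seed = 42)))
    cache
  }
})

sphereFn <- function(x) sum(x^2)
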