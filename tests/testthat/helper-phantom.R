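# Shared fixtures, generated in code.

protocolParadigm <- function() buildParadigm()

# Phantom acquisitions reused across test files (built once per test run).
noiselessPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- phantomTruth(noiseSd = 0)
      cache <<- list(truth = truth,
                     series = generatePhantom(truth, protocolParadigm()))
    }
    cache
  }
})

# wrap a single echo of a MultiEchoSeries as a VoxelSeries
asVoxelSeries <- function(me, echo = 2L) {
  new("VoxelSeries", data = me@data[, , , , echo, drop = TRUE],
      trS = me@trS, labelParity = me@labelParity,
      voxelSizeMm = me@voxelSizeMm)
}

# small synthetic multi-echo series with exact exponential decay
syntheticExpSeries <- function(s0 = 1000, t2star = 30,
                               teMs = c(9.1, 25, 39.6, 54.3),
                               dims = c(3L, 3L, 2L), nFr = 8L) {
  data <- array(0, c(dims, nFr, length(teMs)))
  for (e in seq_along(teMs)) data[, , , , e] <- s0 * exp(-teMs[e] / t2star)
  new("MultiEchoSeries", data = data, teMs = teMs, trS = 4,
      labelParity = "even-control", voxelSizeMm = c(3, 3, 3))
}

unsmoothedConfig <- function(...) fillRunConfig(list(fwhm_mm = 0, ...))
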