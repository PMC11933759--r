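# shared fixtures, built in code

flatSpectrum <- function(value = 1, freqs = seq(0.5, 30, 0.25)) {
  new("PowerSpectrum", freqs = freqs, psd = rep(value, length(freqs)),
      df = freqs[2] - freqs[1], meta = list())
}

curveSpectrum <- function(params, freqs = seq(0.5, 30, 0.25), bumps = NULL) {
  y <- aperiodicCurve(freqs, params)
  if (!is.null(bumps))
    for (i in seq_len(nrow(bumps)))
      y <- y + bumps$amplitude[i] *
        exp(-(freqs - bumps$center[i])^2 / (2 * bumps$bandwidth[i]^2))
  new("PowerSpectrum", freqs = freqs, psd = y, df = freqs[2] - freqs[1],
      meta = list())
}

# tiny all-three-months design for fast end-to-end runs
smallDesign <- function(n = 4) {
  cohortDesign(stats::setNames(rep(list(1:3), n),
                               sprintf("S%02d", seq_len(n))))
}

testRecording <- function(samples, fs = 512, id = "T01", month = 1L,
                          condition = "closed") {
  if (is.null(dim(samples))) samples <- cbind(samples, samples)
  colnames(samples) <- NULL
  new("EEGRecording", participantId = id, month = month,
      condition = condition, channels = c("FP1", "FP2"),
      samples = samples, fs = fs)
}

# one spectrum-mode cohort per session, reused by read-only tests
defaultSpectrumCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateCohort(seed = 1, mode = "spectrum")
    cache
  }
})
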