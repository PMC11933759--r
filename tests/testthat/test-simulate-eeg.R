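test_that("signal specifications are validated", {
  ap <- c(a = 0.08, b = 30, c = 1, d = 2)
  expect_error(signalSpec(ap, data.frame(center = 10, amplitude = -1,
                                         bandwidth = 1)), "amplitudes")
  expect_error(signalSpec(ap, data.frame(center = 40, amplitude = 1,
                                         bandwidth = 1)), "centers")
  expect_error(signalSpec(ap, condition = "blink"), "condition")
  expect_s4_class(signalSpec(ap), "SignalSpec")
})

test_that("synthesis is seeded and has the requested length", {
  sp <- signalSpec(c(a = 0.08, b = 30, c = 1, d = 2), fs = 256,
                   duration = 20)
  x1 <- synthesizeEEG(sp, seed = 4)
  expect_length(x1, 256 * 20)
  expect_identical(x1, synthesizeEEG(sp, seed = 4))
  expect_false(identical(x1, synthesizeEEG(sp, seed = 5)))
})

test_that("a dominant 10 Hz bump puts the spectral peak at 10 Hz", {
  sp <- signalSpec(c(a = 0.05, b = 2, c = 1, d = 2),
                   data.frame(center = 10, amplitude = 2, bandwidth = 0.7),
                   fs = 256, duration = 120)
  x <- synthesizeEEG(sp, seed = 7)
  ep <- matrix(x[seq_len(1024 * floor(length(x) / 1024))], nrow = 1024)
  ps <- multitaperPSD(ep, fs = 256)
  fr <- freqs(ps)
  sel <- fr >= 5 & fr <= 30
  expect_lt(abs(fr[sel][which.max(psd(ps)[sel])] - 10), 0.5)
})

test_that("with no oscillation the periodic residual is negligible", {
  sp <- signalSpec(c(a = 0.08, b = 30, c = 1, d = 2), fs = 256,
                   duration = 200)
  x <- synthesizeEEG(sp, seed = 3, deviceFilter = FALSE)
  ep <- matrix(x[seq_len(1024 * floor(length(x) / 1024))], nrow = 1024)
  dec <- decomposeSpectrum(multitaperPSD(ep, fs = 256))
  sel <- freqs(dec) >= 7 & freqs(dec) <= 13
  relResid <- abs(sum(dec@periodic[sel])) / sum(dec@raw[sel])
  expect_lt(relResid, 0.05)
})

test_that("the log-log flank slope matches the generating exponent", {
  sp <- signalSpec(c(a = 0, b = 30, c = 1e-6, d = 2), fs = 256,
                   duration = 400)
  x <- synthesizeEEG(sp, seed = 9, deviceFilter = FALSE)
  ep <- matrix(x[seq_len(1024 * floor(length(x) / 1024))], nrow = 1024)
  ps <- multitaperPSD(ep, fs = 256)
  sel <- freqs(ps) >= 15 & freqs(ps) <= 30
  slope <- stats::coef(stats::lm(log10(psd(ps)[sel]) ~
                                   log10(freqs(ps)[sel])))[2]
  expect_lt(abs(slope - (-2)), 0.15)
})

test_that("expected PSD of the synthesis matches the target curve", {
  # 200 averaged 4 s epochs; integrated band error below 5 percent
  sp <- signalSpec(c(a = 0.08, b = 30, c = 1, d = 2),
                   data.frame(center = 10, amplitude = 0.8, bandwidth = 0.7),
                   fs = 256, duration = 800)
  x <- synthesizeEEG(sp, seed = 10, deviceFilter = FALSE)
  ep <- matrix(x, nrow = 1024)
  ps <- multitaperPSD(ep, fs = 256)
  fr <- freqs(ps)
  # bands start at 4 Hz: below that the multitaper bandwidth (nw/T =
  # 0.75 Hz) smooths the steep 1/f curvature into a visible upward bias
  for (band in list(c(4, 8), c(8, 13), c(13, 30))) {
    sel <- fr >= band[1] & fr <= band[2]
    est <- sum(psd(ps)[sel])
    tgt <- sum(targetPSD(sp, fr[sel]))
    expect_lt(abs(est / tgt - 1), 0.05)
  }
})

test_that("spectrum-level sampling is an unbiased gamma-noise emulation", {
  sp <- signalSpec(c(a = 0.08, b = 30, c = 1, d = 2))
  grid <- seq(0.5, 30, 0.25)
  obs <- sapply(1:300, function(s)
    psd(samplePowerSpectrum(sp, grid, seed = s)))
  tgt <- targetPSD(sp, grid)
  expect_lt(max(abs(rowMeans(obs) / tgt - 1)), 0.05)
  # per-bin coefficient of variation ~ 1/sqrt(225)
  cv <- apply(obs / tgt, 1, sd)
  expect_lt(abs(median(cv) - 1 / 15), 0.02)
})
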