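test_that("the bandpass preserves mid-band tones and removes DC and
           out-of-band tones", {
  fs <- 512; t <- seq_len(fs * 8) / fs
  rms <- function(x) sqrt(mean(x^2))
  mid <- testRecording(sin(2 * pi * 10 * t), fs = fs)
  out <- bandpassFilter(mid)
  expect_lt(abs(rms(out@samples[, 1]) / rms(mid@samples[, 1]) - 1), 0.05)
  hi <- testRecording(sin(2 * pi * 60 * t), fs = fs)
  att <- 20 * log10(rms(bandpassFilter(hi)@samples[, 1]) /
                      rms(hi@samples[, 1]))
  expect_lt(att, -30)
  dc <- testRecording(rep(100, fs * 16), fs = fs)
  mid <- (fs * 4):(fs * 12)          # away from filtfilt edge transients
  expect_lt(mean(abs(bandpassFilter(dc)@samples[mid, 1])), 1)
})

test_that("filtering is linear and validates its cutoffs", {
  fs <- 512
  x <- rnorm(fs * 4)
  r1 <- bandpassFilter(testRecording(x, fs = fs))
  r2 <- bandpassFilter(testRecording(2 * x, fs = fs))
  expect_lt(max(abs(r2@samples - 2 * r1@samples)), 1e-8)
  expect_error(bandpassFilter(testRecording(x, fs = fs), 30, 0.5), "below")
  expect_error(bandpassFilter(testRecording(x, fs = fs), 0.5, 300),
               "Nyquist")
})

test_that("epoching partitions the used portion and rejects short input", {
  rec <- testRecording(matrix(rnorm(512 * 180 * 2), ncol = 2))
  ep <- epochRecording(rec, 4)
  expect_identical(nEpochs(ep), 45L)
  recon <- matrix(aperm(ep@data, c(1, 3, 2)), ncol = 2)
  expect_identical(recon, rec@samples[seq_len(45 * 2048), ])
  short <- testRecording(matrix(rnorm(2000 * 2), ncol = 2))
  expect_error(epochRecording(short, 4), "shorter")
})

test_that("artifact rejection flags exactly the constructed exceedance and
           is an identity at infinite thresholds", {
  set.seed(1)
  rec <- testRecording(matrix(rnorm(512 * 40 * 2, sd = 10), ncol = 2))
  rec@samples[512 * 10 + 5, 1] <- 500          # transient in epoch 3 (4 s)
  ep <- rejectArtifacts(epochRecording(rec, 4))
  expect_identical(which(!keptMask(ep)), 3L)
  expect_identical(ep@rejectionStats$nAmplitude, 1L)
  epInf <- rejectArtifacts(epochRecording(rec, 4), Inf, Inf)
  expect_true(all(keptMask(epInf)))
})

test_that("rejection is idempotent and errors when nothing survives", {
  set.seed(2)
  ep <- epochRecording(testRecording(matrix(rnorm(512 * 20 * 2), ncol = 2)),
                       4)
  r1 <- rejectArtifacts(ep)
  r2 <- rejectArtifacts(r1)
  expect_identical(keptMask(r1), keptMask(r2))
  loud <- epochRecording(testRecording(matrix(rnorm(512 * 20 * 2, sd = 200),
                                              ncol = 2)), 4)
  expect_error(rejectArtifacts(loud, ampThresholdUv = 1), "review")
})

test_that("clean synthetic recordings survive the default thresholds", {
  p <- defaultGeneratorParams(); p$duration <- 60
  coh <- generateCohort(smallDesign(3), params = p, seed = 6, mode = "time")
  keptAll <- vapply(coh@recordings, function(r)
    all(keptMask(rejectArtifacts(epochRecording(bandpassFilter(r), 4)))),
    logical(1))
  expect_gte(mean(keptAll), 0.99)
})
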