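test_that("DPSS tapers are orthonormal with high in-band concentration", {
  tp <- dpssTapers(2048, 3, 5)
  gram <- crossprod(tp$tapers)
  expect_lt(max(abs(gram - diag(5))), 1e-8)
  expect_true(all(tp$concentrations > 0.9))
  expect_error(dpssTapers(2048, 3, 6), "2\\*nw-1")
})

test_that("the multitaper density integrates to the signal variance", {
  set.seed(3)
  x <- matrix(rnorm(1024 * 60), nrow = 1024)       # unit-variance white
  ps <- multitaperPSD(x, fs = 256)
  expect_lt(abs(sum(psd(ps)) * ps@df - mean(apply(x, 2, var))), 0.05)
})

test_that("a sinusoid's band-integrated power equals A^2/2", {
  fs <- 256; A <- 3
  t <- seq_len(1024 * 30) / fs
  x <- matrix(A * sin(2 * pi * 10 * t), nrow = 1024)
  ps <- multitaperPSD(x, fs = fs)
  sel <- freqs(ps) >= 9 & freqs(ps) <= 11
  expect_lt(abs(sum(psd(ps)[sel]) * ps@df / (A^2 / 2) - 1), 0.05)
})

test_that("zero input yields an identically zero density", {
  ps <- multitaperPSD(matrix(0, 1024, 3), fs = 256)
  expect_identical(max(psd(ps)), 0)
})

test_that("multitaper averaging reduces estimator variance below the
           single-taper periodogram", {
  set.seed(4)
  x <- matrix(rnorm(1024 * 40), nrow = 1024)
  mt <- apply(x, 2, function(e)
    psd(multitaperPSD(matrix(e, ncol = 1), fs = 256)))
  pg <- apply(x, 2, function(e)
    psd(multitaperPSD(matrix(e, ncol = 1), fs = 256, nw = 1, k = 1)))
  mid <- 100:400
  expect_lt(mean(apply(mt[mid, ], 1, var)) / mean(apply(pg[mid, ], 1, var)),
            0.5)
})

test_that("channel averaging is the pointwise mean on a shared grid", {
  ps <- flatSpectrum(2)
  zero <- flatSpectrum(0)
  expect_equal(psd(averageChannels(ps, ps)), psd(ps))
  expect_equal(psd(averageChannels(zero, ps)), rep(1, length(psd(ps))))
  expect_identical(averageChannels(ps, ps)@meta$channel, "FP-mean")
  other <- flatSpectrum(1, freqs = seq(1, 30, 0.25))
  expect_error(averageChannels(ps, other), "grids differ")
})

test_that("relative power reduces to the bandwidth ratio for flat spectra", {
  ps <- flatSpectrum(3.7)
  expect_equal(relativePower(ps, c(7, 8.5)), 1.5 / 29.5, tolerance = 1e-12)
  expect_equal(relativePower(ps, c(0.5, 30)), 1)
  supported <- flatSpectrum(0)
  supported@psd[freqs(supported) >= 7 & freqs(supported) <= 8.5] <- 5
  expect_gt(relativePower(supported, c(6.75, 8.75)), 0.999)
  expect_error(relativePower(flatSpectrum(0), c(7, 8.5)), "zero")
  expect_error(relativePower(ps, c(0.1, 8)), "within totalBand")
})

test_that("relative powers are scale-invariant and additive over adjacent
           bands", {
  coh <- defaultSpectrumCohort()
  ps <- coh@recordings[[10]]
  scaled <- ps; scaled@psd <- ps@psd * 37
  for (b in list(c(7, 8.5), c(9, 10.5), c(8, 13)))
    expect_equal(relativePower(scaled, b), relativePower(ps, b),
                 tolerance = 1e-12)
  lhs <- relativePower(ps, c(7, 8.5)) + relativePower(ps, c(8.5, 10))
  expect_equal(lhs, relativePower(ps, c(7, 10)), tolerance = 1e-12)
})

test_that("the binned relative-power spectrum tiles its range and sums
           to one over the full band", {
  coh <- defaultSpectrumCohort()
  ps <- coh@recordings[[5]]
  bins <- relativePowerSpectrum(ps)
  expect_identical(nrow(bins), 50L)
  expect_identical(bins$f_lo[1], 5)
  expect_identical(bins$f_hi[50], 30)
  full <- relativePowerSpectrum(ps, range = c(0.5, 30))
  expect_lt(abs(sum(full$relPower) - 1), 1e-10)
  bump <- curveSpectrum(c(a = 0.1, b = 1, c = 1, d = 2),
                        bumps = data.frame(center = 10, amplitude = 5,
                                           bandwidth = 0.6))
  bb <- relativePowerSpectrum(bump)
  best <- bb[which.max(bb$relPower), ]
  expect_true(best$f_lo <= 10 && best$f_hi >= 10)
})
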