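test_that("a noiseless model spectrum is recovered essentially exactly", {
  truth <- c(a = 0.1, b = 50, c = 10, d = 2)
  ft <- fitAperiodic(curveSpectrum(truth))
  expect_true(ft@converged)
  expect_lt(ft@rmseLog, 1e-6)
  expect_lt(abs(aperiodicParams(ft)[["d"]] - 2), 0.05)
})

test_that("an oscillatory peak is masked out of the background fit", {
  truth <- c(a = 0.1, b = 50, c = 10, d = 2)
  ps <- curveSpectrum(truth, bumps = data.frame(center = 10, amplitude = 0.5,
                                                bandwidth = 0.7))
  ft <- fitAperiodic(ps)
  expect_lt(abs(aperiodicParams(ft)[["d"]] - 2), 0.1)
})

test_that("non-positive densities in the fit range are a precondition error", {
  ps <- flatSpectrum(1)
  ps@psd[50] <- 0
  expect_error(fitAperiodic(ps), "strictly positive")
})

test_that("the decomposition identity holds to near machine precision", {
  coh <- defaultSpectrumCohort()
  dec <- decomposeSpectrum(coh@recordings[[3]])
  relErr <- max(abs(dec@raw - dec@aperiodic - dec@periodic)) / max(dec@raw)
  expect_lt(relErr, 1e-12)
  expect_true(all(dec@aperiodic > 0))
})

test_that("component band powers share the raw denominator and add up", {
  coh <- defaultSpectrumCohort()
  for (rid in names(coh@recordings)[c(1, 40, 120)]) {
    dec <- decomposeSpectrum(coh@recordings[[rid]])
    for (b in list(c(7, 8.5), c(8, 13))) {
      cp <- componentBandPower(dec, b)
      expect_equal(cp[["raw"]], cp[["aperiodic"]] + cp[["periodic"]],
                   tolerance = 1e-12)
    }
  }
})

test_that("a peak-free spectrum has zero periodic share and a known injected
           bump is recovered in the periodic component", {
  truth <- c(a = 0.08, b = 30, c = 1, d = 2)
  dec0 <- decomposeSpectrum(curveSpectrum(truth))
  cp0 <- componentBandPower(dec0, c(8, 13))
  expect_lt(abs(cp0[["periodic"]]), 1e-6 * cp0[["raw"]])
  expect_equal(cp0[["aperiodic"]], cp0[["raw"]], tolerance = 1e-6)
  amp <- 0.6; bw <- 0.6
  ps <- curveSpectrum(truth, bumps = data.frame(center = 10, amplitude = amp,
                                                bandwidth = bw))
  dec <- decomposeSpectrum(ps)
  sel <- freqs(dec) >= 10 - 2 * bw & freqs(dec) <= 10 + 2 * bw
  got <- sum(dec@periodic[sel]) * 0.25
  injected <- amp * bw * sqrt(2 * pi) * 0.9545
  expect_lt(abs(got / injected - 1), 0.2)
})

test_that("the fit is scale-equivariant", {
  truth <- c(a = 0.1, b = 40, c = 5, d = 2.2)
  ps <- curveSpectrum(truth, bumps = data.frame(center = 10, amplitude = 0.4,
                                                bandwidth = 0.7))
  lam <- 100
  scaled <- ps; scaled@psd <- ps@psd * lam
  p1 <- aperiodicParams(fitAperiodic(ps))
  p2 <- aperiodicParams(fitAperiodic(scaled))
  expect_lt(abs(p2[["a"]] / p1[["a"]] / lam - 1), 0.05)
  expect_lt(abs(p2[["b"]] / p1[["b"]] / lam - 1), 0.05)
  expect_lt(abs(p2[["d"]] - p1[["d"]]), 0.05)
})

test_that("steeper generating spectra never fit shallower", {
  ds <- c(1.5, 2, 2.5)
  fitted <- vapply(ds, function(d) {
    ps <- curveSpectrum(c(a = 0.08, b = 30, c = 1, d = d),
                        bumps = data.frame(center = 10, amplitude = 0.5,
                                           bandwidth = 0.7))
    aperiodicParams(fitAperiodic(ps))[["d"]]
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})
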