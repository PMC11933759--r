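test_that("a cohort is bit-identical under the same master seed", {
  c1 <- generateCohort(smallDesign(3), seed = 8, mode = "spectrum")
  c2 <- generateCohort(smallDesign(3), seed = 8, mode = "spectrum")
  expect_identical(c1@psqi, c2@psqi)
  expect_identical(lapply(c1@recordings, psd), lapply(c2@recordings, psd))
  c3 <- generateCohort(smallDesign(3), seed = 9, mode = "spectrum")
  expect_false(identical(psd(c1@recordings[[1]]), psd(c3@recordings[[1]])))
})

test_that("time-mode recordings are seeded and per-participant stable", {
  p <- defaultGeneratorParams()
  p$duration <- 8
  c1 <- generateCohort(smallDesign(2), params = p, seed = 3, mode = "time")
  c2 <- generateCohort(smallDesign(2), params = p, seed = 3, mode = "time")
  expect_identical(c1@recordings[["S01_m1_closed"]]@samples,
                   c2@recordings[["S01_m1_closed"]]@samples)
  expect_identical(dim(c1@recordings[[1]]@samples), c(8L * 512L, 2L))
})

test_that("eyes-closed alpha relative power exceeds eyes-open every month", {
  coh <- defaultSpectrumCohort()
  for (m in 1:3) {
    sel <- coh@psqi[coh@psqi$month == m, ]
    rp <- function(cond) vapply(sel$participant, function(id)
      relativePower(coh@recordings[[sprintf("%s_m%d_%s", id, m, cond)]],
                    c(8, 13)), numeric(1))
    expect_gt(mean(rp("closed")), mean(rp("open")))
  }
})

test_that("ground-truth low-alpha coupling carries through to the latent table", {
  coh <- defaultSpectrumCohort()
  tr <- coh@truth
  rc <- cor(tr$zla[tr$condition == "closed"], tr$zpm[tr$condition == "closed"])
  ro <- cor(tr$zla[tr$condition == "open"], tr$zpm[tr$condition == "open"])
  # latent correlations near their nominal rho values (n = 92)
  expect_lt(abs(rc - defaultCoupling()$rhoClosed), 0.2)
  expect_lt(abs(ro - defaultCoupling()$rhoOpen), 0.25)
  expect_gt(rc, ro)
})

test_that("null coupling leaves the recovered pooled correlation near zero", {
  cp <- defaultCoupling()
  cp$rhoClosed <- 0; cp$rhoOpen <- 0
  rs <- vapply(1:12, function(s) {
    coh <- generateCohort(coupling = cp, seed = 1000 + s, mode = "spectrum")
    sleepalpha:::pooledLaCorrelation(coh, "closed")
  }, numeric(1))
  expect_gte(sum(abs(rs) < 0.2), 10)     # ~95 percent expected under null
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("recovered correlation grows monotonically with rho", {
  meanR <- function(rho) {
    cp <- defaultCoupling(); cp$rhoClosed <- rho
    mean(vapply(1:10, function(s) {
      coh <- generateCohort(coupling = cp, seed = 300 + s, mode = "spectrum")
      sleepalpha:::pooledLaCorrelation(coh, "closed")
    }, numeric(1)))
  }
  r <- vapply(c(0.2, 0.5, 0.8), meanR, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("coupling calibration hits an attainable target and rejects an
           unattainable one", {
  cal <- calibrateCoupling(0.25, "closed", tol = 0.06, seed = 2, nRep = 6,
                           maxIter = 6)
  expect_lt(abs(cal$realized - 0.25), 0.06)
  expect_gt(cal$rho, 0)
  expect_error(calibrateCoupling(0.97, "closed", tol = 0.02, seed = 2,
                                 nRep = 4), "unattainable")
  cal0 <- calibrateCoupling(0, "closed", seed = 2, nRep = 4)
  expect_identical(cal0$rho, 0)
})

test_that("invalid coupling values are rejected", {
  cp <- defaultCoupling(); cp$rhoClosed <- 1.2
  expect_error(generateCohort(smallDesign(2), coupling = cp,
                              mode = "spectrum"), "\\[-1, 1\\]")
})
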