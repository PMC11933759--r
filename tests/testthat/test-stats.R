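test_that("pearsonCorr matches hand-computed and degenerate cases", {
  ct <- pearsonCorr(c(1, 2, 3), c(1, 2, 4))
  expect_equal(ct$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)  # 0.98198
  lin <- pearsonCorr(1:20, 2 * (1:20) + 1)
  expect_equal(lin$r, 1)
  expect_lt(lin$p, 1e-12)
  expect_equal(pearsonCorr(1:10, -(1:10))$r, -1)
  expect_error(pearsonCorr(1:10, rep(2, 10)), "zero variance")
  expect_error(pearsonCorr(1:3, 1:4), "equal length")
})

test_that("pearsonCorr agrees with cor.test and respects affine maps", {
  set.seed(10)
  x <- rnorm(40); y <- x + rnorm(40)
  ours <- pearsonCorr(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(c(ours$ciLo, ours$ciHi), as.numeric(ref$conf.int),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(ours$ciLo <= ours$r && ours$r <= ours$ciHi)
  shifted <- pearsonCorr(3 * x + 7, y)
  expect_equal(shifted$r, ours$r, tolerance = 1e-12)
  expect_equal(pearsonCorr(-x, y)$r, -ours$r, tolerance = 1e-12)
})

test_that("pairedT matches hand computation, t.test, and is antisymmetric", {
  ht <- pairedT(c(2, 3, 4), c(1, 1, 1))
  expect_equal(ht$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)     # 3.4641
  expect_identical(ht$df, 2)
  eq <- pairedT(1:5, 1:5)
  expect_identical(eq$t, 0)
  expect_identical(eq$p, 1)
  set.seed(11)
  a <- rnorm(25); b <- rnorm(25)
  ours <- pairedT(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(pairedT(b, a)$t, -ours$t, tolerance = 1e-12)
  expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("bonferroni caps at one and matches p.adjust for full families", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(0.2), 0.2)
  p <- c(0.001, 0.02, 0.4)
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
  expect_error(bonferroni(p, m = 2), "at least")
})

test_that("the matched-pairs sample-size search reproduces the reference
           values and is monotone", {
  expect_identical(sampleSizeMatchedPairs(0.65, 0.05, 0.95, tails = 1), 28L)
  expect_identical(sampleSizeMatchedPairs(0.5, 0.05, 0.80, tails = 2), 34L)
  expect_identical(sampleSizeMatchedPairs(10, 0.05, 0.95, tails = 1), 2L)
  # cross-check against the noncentral-t machinery in power.t.test
  for (dz in c(0.3, 0.5, 0.8)) {
    ref <- as.integer(ceiling(power.t.test(delta = dz, sd = 1,
                                           sig.level = 0.05, power = 0.9,
                                           type = "one.sample")$n))
    expect_identical(sampleSizeMatchedPairs(dz, 0.05, 0.9, tails = 2), ref)
  }
  expect_gte(sampleSizeMatchedPairs(0.4, 0.05, 0.95),
             sampleSizeMatchedPairs(0.65, 0.05, 0.95))
  expect_gte(sampleSizeMatchedPairs(0.65, 0.05, 0.99),
             sampleSizeMatchedPairs(0.65, 0.05, 0.95))
})

test_that("the correlation spectrum flags about the nominal rate under null
           coupling and rejects constant PSQI", {
  cp <- defaultCoupling(); cp$rhoClosed <- 0; cp$rhoOpen <- 0
  coh <- generateCohort(coupling = cp, seed = 77, mode = "spectrum")
  binRows <- do.call(rbind, lapply(names(coh@recordings), function(rid) {
    ps <- coh@recordings[[rid]]
    cbind(data.frame(participant = ps@meta$participant,
                     month = ps@meta$month, condition = ps@meta$condition),
          relativePowerSpectrum(ps))
  }))
  cs <- correlationSpectrum(binRows, coh@psqi)
  perMonth <- cs[cs$grouping != "mean", ]
  expect_identical(nrow(perMonth), 50L * 3L * 2L)
  expect_lt(mean(perMonth$sig), 0.12)              # ~5 percent nominal
  constant <- coh@psqi
  constant$psqi_total <- 7L
  expect_error(correlationSpectrum(binRows, constant), "zero variance")
})

test_that("band correlations cover every grouping cell with correct
           complete-subgroup sizes", {
  coh <- defaultSpectrumCohort()
  bp <- do.call(rbind, lapply(names(coh@recordings), function(rid) {
    ps <- coh@recordings[[rid]]
    data.frame(participant = ps@meta$participant, month = ps@meta$month,
               condition = ps@meta$condition, band = "LA",
               component = "raw",
               relPower = relativePower(ps, c(7, 8.5)))
  }))
  tab <- bandCorrelations(bp, coh@psqi,
                          completeIds = completeSubgroup(coh@design))
  expect_identical(nrow(tab), 4L * 2L * 2L)   # grouping x condition x subgroup
  cm <- tab[tab$subgroup == "complete" & tab$grouping != "pooled", ]
  expect_true(all(cm$n == 22L))
  pooledAll <- tab[tab$subgroup == "all" & tab$grouping == "pooled", ]
  expect_true(all(pooledAll$n == 92L))
})

test_that("paired-t type-I error sits at the nominal level", {
  set.seed(12)
  hits <- vapply(seq_len(2000), function(i) {
    a <- rnorm(12); b <- rnorm(12)
    pairedT(a, b)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.035)
  expect_lt(mean(hits), 0.065)
})
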