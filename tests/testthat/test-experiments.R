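test_that("GLM SNR sweeps aggregate oriented log Bayes factors and are
           reproducible", {
  sw <- glmSnrSweep(c(0.05, 0.5), reps = 25, trueModel = "full", seed = 3,
                    nScans = 96)
  tab <- sweepTable(sw)
  expect_equal(nrow(tab), 6)                       # 2 grid x 3 criteria
  expect_setequal(unique(tab$criterion), c("FL", "AIC", "BIC"))
  expect_true(all(is.finite(tab$logBF)))
  sw2 <- glmSnrSweep(c(0.05, 0.5), reps = 25, trueModel = "full", seed = 3,
                     nScans = 96)
  expect_identical(sweepTable(sw2), tab)
  # degenerate single-replication sweeps still return finite numbers
  sw1 <- glmSnrSweep(0.5, reps = 1, trueModel = "nested", seed = 1,
                     nScans = 96)
  expect_true(all(is.finite(sweepTable(sw1)$logBF)))
})

test_that("free-energy sensitivity increases with SNR for full-generated
           data", {
  sw <- glmSnrSweep(c(0.05, 0.15, 0.3, 0.6, 1.2), reps = 60,
                    trueModel = "full", seed = 5, nScans = 128)
  tab <- sweepTable(sw)
  fl <- tab$logBF[tab$criterion == "FL"]
  expect_gt(cor(fl, sort(unique(tab$axisValue)), method = "spearman"), 0.9)
})

test_that("orientation is antisymmetric between full- and nested-favouring
           scores", {
  # the same replication scored both ways flips sign exactly
  X <- makeGlmDesign(nScans = 96, seed = 2)
  Xn <- X[, -(1:3)]
  snr <- calibrateSnr(glmPriorSignals(X, 6.05, 100, seed = 2), 0.5)
  ds <- generateGlmDataset(X, 6.05, snr, seed = 7)
  cf <- glmCriteria(glmSpec(X, 6.05, snr@noiseSd), ds$y)$criteria
  cn <- glmCriteria(glmSpec(Xn, 6.05, snr@noiseSd), ds$y)$criteria
  expect_equal(bayesFactor(cf@fL, cn@fL)$logBF,
               -bayesFactor(cn@fL, cf@fL)$logBF)
  expect_equal(bayesFactor(cf@aic, cn@aic)$logBF, cf@aic - cn@aic)
})

test_that("N sweeps include AICc, enforce its domain, and converge to
           AIC at large N", {
  expect_error(glmNSweep(nGrid = c(10, 64), reps = 2), "p \\+ 1")
  sw <- glmNSweep(nGrid = c(32, 128, 512), reps = 30, trueModel = "full",
                  seed = 11)
  tab <- sweepTable(sw)
  expect_setequal(unique(tab$criterion), c("FL", "AIC", "BIC", "AICc"))
  gap <- vapply(c(32, 128, 512), function(n)
    abs(tab$logBF[tab$axisValue == n & tab$criterion == "AICc"] -
          tab$logBF[tab$axisValue == n & tab$criterion == "AIC"]), 0)
  expect_true(all(diff(gap) < 0))
  # evidence for the true full model grows with more data
  fl <- tab$logBF[tab$criterion == "FL"]
  expect_gt(fl[3], fl[1])
})

test_that("DCM sweeps report exclusions and run at reduced scale", {
  sw <- dcmSnrSweep(2, reps = 2, trueModel = "full", seed = 21,
                    nScans = 64)
  tab <- sweepTable(sw)
  expect_equal(nrow(tab), 3)
  expect_true(all(is.finite(tab$logBF)))
  expect_true(all(tab$excluded >= 0 & tab$excluded <= 2))
  expect_equal(sw@aggregator, "median")
})

test_that("comparison decomposition is exact for identical fits and guards
           against mismatched data", {
  ms <- smallSpeechModels(nScans = 48)
  ds <- generateDcmDataset(ms$full, snr = 1, seed = 2)
  fit <- dcmFit(ms$full, ds$y, ds$inputs)
  dec <- decomposeComparison(fit, fit)
  expect_equal(dec$deltaFL, 0)
  expect_true(all(dec$regionAccuracy$delta == 0))
  expect_true(all(dec$setComplexity$delta == 0))
  ds2 <- generateDcmDataset(ms$full, snr = 1, seed = 3)
  fit2 <- dcmFit(ms$full, ds2$y, ds2$inputs)
  expect_error(decomposeComparison(fit, fit2), "different data")
})
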