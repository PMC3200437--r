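test_that("default design emulates the four-condition three-basis layout", {
  X <- makeGlmDesign(seed = 1)
  expect_equal(dim(X), c(351L, 12L))
  expect_equal(qr(X)$rank, 12)
  # condition-major columns: dropping condition 1 = dropping columns 1:3
  expect_equal(colnames(X)[1:3], c("c1.b1", "c1.b2", "c1.b3"))
  # same seed, same design, to the last bit
  expect_identical(X, makeGlmDesign(seed = 1))
  expect_false(identical(X, makeGlmDesign(seed = 2)))
})

test_that("explicit schedules are honoured and validated", {
  sched <- data.frame(onset = c(10, 50, 90), condition = c(1, 2, 1))
  X <- makeGlmDesign(nScans = 64, conditions = 2, TR = 2,
                     schedule = sched)
  expect_equal(dim(X), c(64L, 6L))
  expect_gt(max(abs(X[, 1:3])), 0)
  empty <- makeGlmDesign(nScans = 32, schedule = data.frame(
    onset = numeric(0), condition = integer(0)))
  expect_true(all(empty == 0))
  expect_error(makeGlmDesign(nScans = 32, TR = 2, schedule = data.frame(
    onset = 100, condition = 1)), "exceeds")
})

test_that("SNR calibration implements signal SD over noise SD", {
  sig <- matrix(rnorm(400, sd = 2), 100, 4)
  spec <- calibrateSnr(sig, targetSnr = 0.5)
  expect_equal(spec@noiseSd, spec@signalSd / 0.5)
  expect_equal(spec@targetSnr, 0.5)
  # scale equivariance: doubling all signals doubles the noise SD
  spec2 <- calibrateSnr(2 * sig, targetSnr = 0.5)
  expect_equal(spec2@noiseSd, 2 * spec@noiseSd)
  expect_error(calibrateSnr(matrix(1, 10, 2), 1), "constant")
})

test_that("GLM data sets are prior draws plus calibrated noise", {
  X <- makeGlmDesign(nScans = 128, seed = 3)
  snrSpec <- calibrateSnr(glmPriorSignals(X, 6.05, 200, seed = 4), 0.5)
  d1 <- generateGlmDataset(X, 6.05, snrSpec, seed = 9)
  d2 <- generateGlmDataset(X, 6.05, snrSpec, seed = 9)
  expect_identical(d1, d2)                      # bit-reproducible
  # near-zero noise: y equals the noiseless prediction
  tiny <- calibrateSnr(glmPriorSignals(X, 6.05, 50, seed = 4), 1e9)
  d3 <- generateGlmDataset(X, 6.05, tiny, seed = 9)
  expect_equal(d3$y, drop(X %*% d3$theta), tolerance = 1e-6)
  # realised residual SD matches sigma_e over replications
  resid <- unlist(lapply(1:200, function(s) {
    d <- generateGlmDataset(X, 6.05, snrSpec, seed = s)
    d$y - drop(X %*% d$theta)
  }))
  expect_equal(sd(resid), snrSpec@noiseSd, tolerance = 0.02)
})

test_that("DCM data sets obey positivity, nesting and the target SNR", {
  ms <- smallSpeechModels(nScans = 64)
  snrs <- numeric(0)
  for (seed in 1:25) {
    ds <- generateDcmDataset(ms$full, snr = 1, seed = seed)
    b <- ds$params@B[[2]]
    expect_gte(b[2, 1], 0)
    expect_gte(b[3, 1], 0)
    snrs <- c(snrs, ds$snrSpec@signalSd / ds$snrSpec@noiseSd)
  }
  expect_true(all(abs(snrs - 1) < 0.05))
  dsN <- generateDcmDataset(ms$nested, snr = 1, seed = 3)
  expect_identical(dsN$params@B[[2]][3, 1], 0)
  # same seed reproduces the data exactly
  a <- generateDcmDataset(ms$full, snr = 2, seed = 5)
  b2 <- generateDcmDataset(ms$full, snr = 2, seed = 5)
  expect_identical(boldValues(a$ts), boldValues(b2$ts))
})

test_that("default DCM geometry matches the speech study dimensions", {
  ms <- buildSpeechModels()
  ds <- generateDcmDataset(ms$full, snr = 2, seed = 1)
  expect_equal(dim(boldValues(ds$ts)), c(488L, 3L))
  expect_length(ds$y, 488L * 3L)
})
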