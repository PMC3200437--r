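test_that("numerical Jacobian matches analytic derivatives", {
  X <- matrix(rnorm(30), 10, 3)
  J <- numericalJacobian(function(th) drop(X %*% th), c(0.3, -1, 2))
  expect_equal(J, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(drop(numericalJacobian(function(x) x^2, 3)), 6,
               tolerance = 1e-6)
  # columns are produced for every coordinate, even ones a prior may fix
  J2 <- numericalJacobian(function(th) th[1] * c(1, 2), c(1, 5))
  expect_equal(dim(J2), c(2, 2))
  expect_true(all(J2[, 2] == 0))
  expect_error(numericalJacobian(function(th) c(NaN, 1), c(0, 0)),
               "non-finite")
})

test_that("on linear models with known noise VL recovers the analytic
           posterior", {
  for (seed in 1:5) {
    inst <- randomGlmInstance(seed)
    X <- inst$spec@design
    n <- nrow(X); d <- ncol(X)
    prior <- gaussianBelief(rep(0, d), inst$spec@priorSd^2)
    nm <- noiseModel(list(seq_len(n)), n,
                     hyperMean = -2 * log(inst$spec@noiseSd), hyperCov = 0)
    fit <- vlFit(function(th) drop(X %*% th), prior, nm, inst$y,
                 options = list(estimateHyper = FALSE))
    ana <- glmPosterior(inst$spec, inst$y)
    expect_lt(max(abs(posteriorMean(fit) - beliefMean(ana))), 1e-5)
    expect_lt(max(abs(posteriorCov(fit) - beliefCov(ana))), 1e-5)
    expect_equal(freeEnergy(fit), glmLogEvidence(inst$spec, inst$y),
                 tolerance = 1e-6)
    expect_true(isConverged(fit))
  }
})

test_that("zero prior variance pins a parameter at its prior mean", {
  set.seed(8)
  X <- cbind(1, rnorm(25), rnorm(25))
  y <- drop(X %*% c(1, 2, 0)) + rnorm(25, 0, 0.5)
  prior <- gaussianBelief(c(0, 0, 0.7), c(4, 4, 0))
  nm <- noiseModel(list(1:25), 25, hyperMean = log(4), hyperCov = 0)
  fit <- vlFit(function(th) drop(X %*% th), prior, nm, y,
               options = list(estimateHyper = FALSE))
  expect_equal(unname(posteriorMean(fit)[3]), 0.7)
  expect_equal(posteriorCov(fit)[3, ], rep(0, 3), ignore_attr = TRUE)
  # AIC/BIC count only the free parameters
  expect_equal(modelCriteria(fit)@p, 2L)
})

test_that("accepted free-energy trajectory never decreases", {
  set.seed(12)
  th0 <- c(1, -0.5)
  g <- function(th) exp(-th[1] * seq(0, 3, by = 0.1)) + th[2]
  y <- g(c(0.8, -0.3)) + rnorm(31, 0, 0.05)
  fit <- vlFit(g, gaussianBelief(c(0.5, 0), 1),
               regionNoiseModel(31, 1), y)
  expect_true(all(diff(fit@trajectory) >= 0))
  expect_gte(freeEnergy(fit), max(fit@trajectory[-length(fit@trajectory)]))
})

test_that("estimated noise precision approaches the generating precision
           with plenty of data", {
  ms <- buildSpeechModels(nScans = 488, TR = 2)
  spec <- ms$full
  ds <- generateDcmDataset(spec, snr = 1, seed = 31)
  fit <- dcmFit(spec, ds$y, ds$inputs)
  truePrec <- 1 / ds$snrSpec@noiseSd^2
  est <- exp(beliefMean(fit@lambda))
  expect_true(all(abs(est - truePrec) / truePrec <= 0.10))
})

test_that("fitting the nested model to full-generated data inflates the
           F-to-A intrinsic connection", {
  ms <- smallSpeechModels(nScans = 128)
  # a draw with a substantial true P-to-A modulation
  ds <- generateDcmDataset(ms$full, snr = 2, seed = 101)
  expect_gt(ds$params@B[[2]][3, 1], 0.5)
  ff <- dcmFit(ms$full, ds$y, ds$inputs)
  fn <- dcmFit(ms$nested, ds$y, ds$inputs)
  aAFfull <- posteriorMean(ff)["a_AF"]
  aAFnested <- posteriorMean(fn)["a_AF"]
  expect_gt(unname(aAFnested / aAFfull), 2)
  # the criterion that notices is the free energy, through complexity
  dec <- decomposeComparison(ff, fn)
  expect_gt(dec$deltaFL, 0)
  expect_equal(dec$dominantTerm, "complexity")
  # the accuracy advantage of the full model is realised in region A
  ra <- dec$regionAccuracy
  expect_equal(ra$region[which.max(ra$delta)], "A")
})
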