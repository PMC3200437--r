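test_that("accuracy matches hand-evaluated Gaussian log-densities", {
  expect_equal(evidenceAccuracy(0, 1, 1), -0.5 * log(2 * pi))
  expect_equal(evidenceAccuracy(c(1, 1), diag(2), 2), -1 - log(2 * pi))
  # scaling the noise covariance by 4 with zero residual adds -log(4^n)/2
  for (n in c(1, 3, 7)) {
    e <- numeric(n)
    expect_equal(evidenceAccuracy(e, 4 * diag(n), n),
                 evidenceAccuracy(e, diag(n), n) - 0.5 * log(4^n))
  }
  expect_error(evidenceAccuracy(c(0, 0), matrix(c(1, 1, 1, 1), 2), 2),
               "positive definite")
  expect_error(evidenceAccuracy(c(0, 0), diag(3), 2), "dimension")
})

test_that("complexity vanishes when posterior equals prior and grows with
           posterior shrinkage", {
  set.seed(4)
  for (d in c(1, 3, 5)) {
    A <- matrix(rnorm(d * d), d)
    Ct <- crossprod(A) + diag(d)
    cx <- evidenceComplexity(numeric(d), Ct, Ct)
    expect_equal(unname(cx[["params"]]), 0)
    # halving every eigenvalue of the posterior increases complexity
    cxHalf <- evidenceComplexity(numeric(d), Ct, Ct / 2)
    expect_gt(cxHalf[["params"]], cx[["params"]])
  }
  expect_equal(unname(evidenceComplexity(1, 1, 1)[["params"]]), 0.5)
  expect_error(evidenceComplexity(c(1, 2), diag(3), diag(3)), "dimension")
})

test_that("hyperparameter complexity is zero when hypers are known and
           mirrors the parameter form otherwise", {
  cx <- evidenceComplexity(1, 2, 1)
  expect_equal(unname(cx[["hypers"]]), 0)
  cx2 <- evidenceComplexity(1, 2, 1, eLambda = 1, CLambda = 1, SLambda = 1)
  expect_equal(unname(cx2[["hypers"]]), 0.5)
  expect_equal(cx2[["params"]], cx[["params"]])
})

test_that("free energy is accuracy minus complexity with consistent maps", {
  n <- 6
  bd <- laplaceFreeEnergy(numeric(n), 1, n, eTheta = 0, CTheta = 1,
                          STheta = 1)
  expect_equal(freeEnergy(bd), -(n / 2) * log(2 * pi))
  set.seed(9)
  ey <- rnorm(n)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  bd2 <- laplaceFreeEnergy(ey, rep(2, n), n,
                           eTheta = rnorm(3), CTheta = diag(3), STheta = S,
                           regionMap = list(a = 1:3, b = 4:6),
                           setMap = list(x = 1:2, y = 3L))
  expect_equal(bd2@fL, bd2@accuracy - bd2@complexityParams -
                 bd2@complexityHypers)
  # per-region accuracies sum exactly to the total for block-diagonal noise
  expect_equal(unname(sum(bd2@accuracyByRegion)), bd2@accuracy)
  # per-set complexity is exact when cross-set correlation is absent
  Sdiag <- diag(diag(S))
  bd3 <- laplaceFreeEnergy(ey, rep(2, n), n, eTheta = c(1, -1, 2),
                           CTheta = diag(3), STheta = Sdiag,
                           setMap = list(x = 1:2, y = 3L))
  expect_equal(unname(sum(bd3@complexityBySet)), bd3@complexityParams)
  expect_error(
    laplaceFreeEnergy(ey, 1, n, eTheta = 0, CTheta = 1, STheta = 1,
                      regionMap = list(a = 1:3)),
    "partition")
})

test_that("two-parameter posterior determinant follows the correlation
           identity", {
  for (r in c(-0.9, -0.3, 0, 0.5, 0.99)) {
    for (s1 in c(0.1, 1)) {
      s2 <- 2.5
      S <- matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2)
      expect_equal(determinant(S, logarithm = TRUE)$modulus[[1]],
                   log((1 - r^2) * s1^2 * s2^2))
      # complexity uses exactly this determinant through its Cholesky
      cx <- evidenceComplexity(c(0, 0), diag(2), S)
      expect_equal(unname(cx[["params"]]),
                   -0.5 * log((1 - r^2) * s1^2 * s2^2))
    }
  }
})

test_that("complexity is invariant to joint rotation of deviation and
           covariances", {
  set.seed(11)
  for (rep in 1:20) {
    d <- sample(2:5, 1)
    e <- rnorm(d)
    Ct <- crossprod(matrix(rnorm(d * d), d)) + diag(d)
    St <- crossprod(matrix(rnorm(d * d), d)) + 0.5 * diag(d)
    Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    cx0 <- evidenceComplexity(e, Ct, St)
    cx1 <- evidenceComplexity(drop(Q %*% e), Q %*% Ct %*% t(Q),
                              Q %*% St %*% t(Q))
    expect_equal(cx1[["params"]], cx0[["params"]], tolerance = 1e-8)
  }
})

test_that("information criteria follow their defining penalties", {
  expect_equal(aic(-50, 0), -50)
  expect_equal(aic(-50, 4), -54)
  expect_equal(bic(-50, 0, 1000), -50)
  expect_equal(bic(-50, 4, 100), -50 - 2 * log(100))
  expect_equal(aicc(-50, 0, 10), aic(-50, 0))
  expect_equal(aicc(-50, 4, 20), -54 - 20 / 15)
  # BIC penalty exceeds AIC's for n > e^2, equals it at n = e^2
  expect_equal(bic(-50, 3, exp(2)), aic(-50, 3))
  expect_lt(bic(-50, 3, 8), aic(-50, 3))
  # AICc approaches AIC as n grows at fixed p
  gaps <- vapply(c(50, 500, 5000), function(n)
    aic(-50, 4) - aicc(-50, 4, n), 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-2)
  expect_error(aic(-50, -1), "p must be")
  expect_error(bic(-50, 2, 0), "n must be")
  expect_error(aicc(-50, 4, 5), "n > p \\+ 1")
})

test_that("Bayes factors convert to posterior probabilities and are
           antisymmetric", {
  b <- bayesFactor(log(20), 0)
  expect_gt(b$posteriorProb1, 0.95)
  expect_equal(round(b$logBF), 3)
  expect_equal(b$bf, 20)
  expect_equal(bayesFactor(-3, -3)$posteriorProb1, 0.5)
  set.seed(2)
  for (rep in 1:25) {
    a <- rnorm(1, sd = 50); bb <- rnorm(1, sd = 50)
    expect_equal(bayesFactor(a, bb)$logBF, -bayesFactor(bb, a)$logBF)
  }
  # huge log Bayes factors stay finite in probability
  expect_equal(bayesFactor(5000, 0)$posteriorProb1, 1)
})

test_that("prior width moves the free energy but not AIC or BIC", {
  set.seed(13)
  X <- matrix(rnorm(60), 20, 3)
  y <- drop(X %*% c(1, 0.5, -1)) + rnorm(20, 0, 0.5)
  c1 <- glmCriteria(glmSpec(X, priorSd = 1, noiseSd = 0.5), y)$criteria
  c2 <- glmCriteria(glmSpec(X, priorSd = 10, noiseSd = 0.5), y)$criteria
  expect_false(isTRUE(all.equal(c1@fL, c2@fL)))
  # identical fixed penalty per parameter: AIC/BIC differ only through the
  # (slightly) different posterior-mean accuracies, with the same penalty
  expect_equal(c1@aic - c1@bic, c2@aic - c2@bic)
  expect_equal(c1@p, c2@p)
})

test_that("evidence records flatten to the documented keys", {
  res <- glmCriteria(glmSpec(matrix(rnorm(20), 10, 2), 1, 1), rnorm(10))
  rec <- asEvidenceRecord(res$breakdown, res$criteria)
  expect_true(all(c("f_l", "accuracy", "complexity_params",
                    "complexity_hypers", "aic", "bic", "aicc", "p", "n")
                  %in% names(rec)))
  expect_equal(rec$f_l, res$criteria@fL)
})
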