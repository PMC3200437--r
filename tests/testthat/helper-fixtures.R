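# Shared fixtures: small random GLM instances and a fast two-region DCM.

# random full-column-rank GLM instance with prior-drawn data
randomGlmInstance <- function(seed, dMax = 6, nMax = 50) {
  set.seed(seed)
  d <- sample(1:dMax, 1)
  n <- sample((d + 2):nMax, 1)
  X <- matrix(rnorm(n * d), n, d)
  sigmaP <- runif(1, 0.3, 5)
  sigmaE <- runif(1, 0.2, 2)
  spec <- glmSpec(X, priorSd = sigmaP, noiseSd = sigmaE)
  theta <- rnorm(d, 0, sigmaP)
  y <- drop(X %*% theta) + rnorm(n, 0, sigmaE)
  list(spec = spec, y = y, theta = theta)
}

# small speech-network spec for fast DCM tests
smallSpeechModels <- function(nScans = 64, TR = 2) {
  buildSpeechModels(nScans = nScans, TR = TR)
}

# joint neuronal + hemodynamic RHS for deSolve, the independent reference
# integrator (adaptive lsoda) for the fixed-step RK4 scheme
dcmOdeRhs <- function(t, state, parms) {
  r <- parms$r
  z <- state[seq_len(r)]
  u <- vapply(seq_len(ncol(parms$uFun)), function(j)
    stats::approx(parms$ut, parms$uFun[, j], t, rule = 2)$y, 0)
  Aeff <- parms$A
  for (j in seq_along(u)) Aeff <- Aeff + u[j] * parms$B[[j]]
  dz <- drop(Aeff %*% z + parms$C %*% u)
  dh <- numeric(4 * r)
  for (i in seq_len(r)) {
    s <- state[r + (i - 1) * 4 + 1]; f <- state[r + (i - 1) * 4 + 2]
    v <- state[r + (i - 1) * 4 + 3]; q <- state[r + (i - 1) * 4 + 4]
    h <- parms$h[i, ]
    fv <- v^(1 / h["alpha"])
    Ef <- 1 - (1 - h["E0"])^(1 / f)
    dh[(i - 1) * 4 + 1] <- z[i] - h["kappa"] * s - h["gamma"] * (f - 1)
    dh[(i - 1) * 4 + 2] <- s
    dh[(i - 1) * 4 + 3] <- (f - fv) / h["tau"]
    dh[(i - 1) * 4 + 4] <- (f * Ef / h["E0"] - fv * q / v) / h["tau"]
  }
  list(c(dz, dh))
}

# reference BOLD via deSolve at tight tolerances
referenceBold <- function(params, spec, inputs) {
  r <- spec@nRegions
  tgrid <- (seq_len(nrow(inputs@u)) - 1) * inputs@dt
  parms <- list(r = r, A = params@A, B = params@B, C = params@C,
                h = params@h, ut = tgrid, uFun = inputs@u)
  y0 <- c(numeric(r), rep(c(0, 1, 1, 1), r))
  scanTimes <- (seq_len(spec@nScans) - 1) * spec@TR
  out <- deSolve::lsoda(y0, scanTimes, dcmOdeRhs, parms,
                        rtol = 1e-9, atol = 1e-10)
  TE <- 0.04; V0 <- 4; theta0 <- 40.3; r0 <- 25
  bold <- sapply(seq_len(r), function(i) {
    v <- out[, 1 + r + (i - 1) * 4 + 3]
    q <- out[, 1 + r + (i - 1) * 4 + 4]
    E0 <- params@h[i, "E0"]; eps <- params@h[i, "epsilon"]
    k1 <- 4.3 * theta0 * E0 * TE; k2 <- eps * r0 * E0 * TE; k3 <- 1 - eps
    V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
  })
  matrix(bold, ncol = r)
}
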