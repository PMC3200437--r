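## Variational Laplace: fixed-form Gaussian posteriors q(theta)q(lambda)
## optimised by Gauss-Newton / Levenberg-Marquardt steps on the parameters
## and Newton steps on the noise log-precisions, with every step accepted
## only if it does not decrease the Laplace free energy.

#' Numerical Jacobian by central differences
#'
#' Per-coordinate central finite differences with relative step
#' \code{max(|theta0[i]|, 1) * relStep}. Columns are computed for every
#' coordinate, including parameters a caller may later hold fixed.
#'
#' @param g vectorised prediction function of the parameter vector.
#' @param theta0 point at which to differentiate.
#' @param relStep relative step size (default 1e-4).
#' @return Matrix with one column per parameter.
#' @examples
#' numericalJacobian(function(x) x^2, 3)  # ~6
#' @export
numericalJacobian <- function(g, theta0, relStep = 1e-4) {
  theta0 <- as.numeric(theta0)
  g0 <- as.numeric(g(theta0))
  if (!all(is.finite(g0)))
    stop("model evaluation returned non-finite values", call. = FALSE)
  J <- matrix(0, length(g0), length(theta0))
  for (i in seq_along(theta0)) {
    hstep <- max(abs(theta0[i]), 1) * relStep
    tp <- theta0; tp[i] <- tp[i] + hstep
    tm <- theta0; tm[i] <- tm[i] - hstep
    gp <- as.numeric(g(tp)); gm <- as.numeric(g(tm))
    if (!all(is.finite(gp)) || !all(is.finite(gm)))
      stop("model evaluation returned non-finite values during ",
           "differentiation", call. = FALSE)
    J[, i] <- (gp - gm) / (2 * hstep)
  }
  J
}

#' Default options for vlFit
#'
#' @param maxIter maximum number of iterations.
#' @param tol convergence tolerance: stop when the free-energy increase is
#'   below \code{tol} for two consecutive iterations.
#' @param jacRelStep relative finite-difference step for the Jacobian.
#' @param maxReject maximum damping retries within one iteration.
#' @param estimateHyper estimate the noise log-precisions (set to
#'   \code{FALSE}, or give a zero hyper-prior covariance, for known noise).
#' @return Named list of options.
#' @export
vlOptions <- function(maxIter = 128L, tol = 1e-2, jacRelStep = 1e-4,
                      maxReject = 12L, estimateHyper = TRUE) {
  list(maxIter = as.integer(maxIter), tol = tol, jacRelStep = jacRelStep,
       maxReject = as.integer(maxReject), estimateHyper = estimateHyper)
}

## diagonal noise precision w (length n) from identity-block bases
.blockPrec <- function(blocks, lam, n) {
  w <- numeric(n)
  for (i in seq_along(blocks)) w[blocks[[i]]] <- w[blocks[[i]]] + exp(lam[i])
  if (any(w <= 0)) stop("noise precision not positive definite", call. = FALSE)
  w
}

## gradient and (negative-definite) Hessian of F_L w.r.t. lambda for
## identity-block bases (blocks may overlap)
.lambdaDerivsBlock <- function(blocks, lam, w, e, iCl, elam) {
  k <- length(blocks)
  grad <- numeric(k)
  Hess <- matrix(0, k, k)
  iw <- 1 / w; iw2 <- iw^2
  for (i in seq_len(k)) {
    bi <- blocks[[i]]
    ri <- sum(e[bi]^2)
    ti <- sum(iw[bi])
    grad[i] <- -0.5 * exp(lam[i]) * ri + 0.5 * exp(lam[i]) * ti
    Hess[i, i] <- -0.5 * exp(lam[i]) * ri + 0.5 * exp(lam[i]) * ti
    for (j in seq_len(k)) {
      sij <- if (i == j) sum(iw2[bi]) else {
        common <- intersect(bi, blocks[[j]])
        if (length(common)) sum(iw2[common]) else 0
      }
      Hess[i, j] <- Hess[i, j] - 0.5 * exp(lam[i] + lam[j]) * sij
    }
  }
  grad <- grad - drop(iCl %*% elam)
  Hess <- Hess - iCl
  list(grad = grad, hess = Hess)
}

## lambda derivatives for full-matrix precision bases (expected curvature)
.lambdaDerivsFull <- function(bases, lam, Pinv, e, iCl, elam) {
  k <- length(bases)
  grad <- numeric(k)
  Hess <- matrix(0, k, k)
  for (i in seq_len(k)) {
    Qi <- bases[[i]]
    grad[i] <- 0.5 * exp(lam[i]) *
      (sum(Pinv * Qi) - drop(crossprod(e, Qi %*% e)))
    for (j in seq_len(k)) {
      Qj <- bases[[j]]
      Hess[i, j] <- -0.5 * exp(lam[i] + lam[j]) *
        sum((Pinv %*% Qi) * t(Pinv %*% Qj))
    }
  }
  list(grad = grad - drop(iCl %*% elam), hess = Hess - iCl)
}

#' Fit a nonlinear model by variational Laplace
#'
#' Maximises the Laplace free energy of the observation model
#' \eqn{y = g(\theta) + e}, \eqn{e \sim N(0, C_y)},
#' \eqn{C_y^{-1} = \sum_i \exp(\lambda_i) Q_i}, under the factorised
#' Gaussian posterior \eqn{q(\theta) q(\lambda)}. Parameters are updated by
#' Gauss-Newton steps with Levenberg-Marquardt damping, hyperparameters by
#' damped Newton steps; a step is accepted only when it does not decrease
#' the free energy, so the accepted trajectory is non-decreasing. Parameters
#' with zero prior variance are held at their prior mean and excluded from
#' the update (and from the AIC/BIC parameter count).
#'
#' @param g prediction function mapping the full parameter vector to a
#'   length-\code{n} prediction.
#' @param prior [GaussianBelief-class] over the full parameter vector
#'   (zero variance marks a fixed parameter).
#' @param noise a [NoiseModel-class].
#' @param y data vector.
#' @param options list from [vlOptions()] (partial lists are merged with
#'   the defaults).
#' @param regionMap,setMap optional partitions passed to
#'   [laplaceFreeEnergy()] for the final breakdown. When \code{regionMap}
#'   is \code{NULL} and the noise bases are disjoint identity blocks, the
#'   blocks are used as regions.
#' @param withAicc also compute AICc.
#' @return A [FitResult-class]. Non-convergence within \code{maxIter}
#'   iterations is reported through the \code{converged} flag, not an error.
#' @examples
#' X <- cbind(1, sin(1:30))
#' y <- drop(X %*% c(1, 2)) + rnorm(30, sd = 0.3)
#' fit <- vlFit(function(th) drop(X %*% th),
#'              gaussianBelief(c(0, 0), 4),
#'              regionNoiseModel(30, 1), y)
#' posteriorMean(fit)
#' @export
vlFit <- function(g, prior, noise, y, options = list(),
                  regionMap = NULL, setMap = NULL, withAicc = FALSE) {
  opt <- utils::modifyList(vlOptions(), options)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(is(prior, "GaussianBelief"), is(noise, "NoiseModel"))
  if (noise@n != n) stop("noise model size must match data", call. = FALSE)

  pv <- diag(prior@cov)
  free <- which(pv > 0)
  if (!length(free)) stop("no free parameters", call. = FALSE)
  muf <- prior@mean[free]
  Cf <- prior@cov[free, free, drop = FALSE]
  iCf <- chol2inv(.cholPD(Cf, "prior covariance"))
  pf <- length(free)

  gFull <- function(tf) {
    th <- prior@mean; th[free] <- tf
    gv <- as.numeric(g(th))
    if (length(gv) != n)
      stop("prediction length does not match data", call. = FALSE)
    gv
  }

  estH <- opt$estimateHyper && any(diag(noise@hyperCov) > 0)
  mul <- noise@hyperMean
  k <- length(mul)
  iCl <- if (estH) chol2inv(.cholPD(noise@hyperCov, "hyper prior")) else
    matrix(0, k, k)
  isBlock <- all(!vapply(noise@bases, is.matrix, TRUE))
  blocks <- if (isBlock) lapply(noise@bases, as.integer) else NULL
  if (is.null(regionMap) && isBlock &&
      sum(lengths(blocks)) == n && !anyDuplicated(unlist(blocks))) {
    regionMap <- blocks
    names(regionMap) <- paste0("region", seq_along(blocks))
  }

  ## free energy and sufficient statistics at (mf, lam); J given at mf
  evalF <- function(mf, lam, gm, J) {
    e <- y - gm
    if (isBlock) {
      w <- .blockPrec(blocks, lam, n)
      Cy <- 1 / w
      JtPJ <- crossprod(J, J * w)
    } else {
      Pi <- Reduce(`+`, Map(function(l, Q) exp(l) * Q, lam, noise@bases))
      Cy <- chol2inv(.cholPD(Pi, "noise precision"))
      JtPJ <- crossprod(J, Pi %*% J)
    }
    H <- JtPJ + iCf
    Rh <- .cholPD(H, "posterior precision")
    Sf <- chol2inv(Rh)
    hyp <- NULL
    Sl <- matrix(0, k, k)
    if (estH) {
      hyp <- if (isBlock)
        .lambdaDerivsBlock(blocks, lam, w, e, iCl, lam - mul)
      else
        .lambdaDerivsFull(noise@bases, lam,
                          chol2inv(.cholPD(Pi, "noise precision")), e, iCl,
                          lam - mul)
      Sl <- chol2inv(.cholPD(-hyp$hess, "hyper posterior precision"))
    }
    bd <- laplaceFreeEnergy(e, Cy, n, eTheta = mf - muf, CTheta = Cf,
                            STheta = Sf,
                            eLambda = if (estH) lam - mul,
                            CLambda = if (estH) noise@hyperCov,
                            SLambda = if (estH) Sl)
    grad <- if (isBlock) crossprod(J, w * e) else crossprod(J, Pi %*% e)
    list(F = bd@fL, e = e, Cy = Cy, H = H, Sf = Sf, Sl = Sl, hyp = hyp,
         grad = drop(grad) - drop(iCf %*% (mf - muf)))
  }

  mf <- muf
  lam <- mul
  lm <- 0
  gm <- gFull(mf)
  J <- numericalJacobian(gFull, mf, opt$jacRelStep)
  st <- evalF(mf, lam, gm, J)
  trajectory <- numeric(0)
  nSmall <- 0L
  iter <- 0L
  converged <- FALSE

  while (iter < opt$maxIter) {
    iter <- iter + 1L
    fStart <- st$F

    ## ---- theta step (Levenberg-Marquardt) ----
    accepted <- FALSE
    for (try in seq_len(opt$maxReject)) {
      Hd <- st$H + lm * diag(diag(st$H), pf)
      delta <- tryCatch(
        drop(backsolve(chol(Hd), backsolve(chol(Hd), st$grad,
                                           transpose = TRUE))),
        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- mf + delta
        ok <- TRUE
        gc2 <- tryCatch(gFull(cand), error = function(e) {ok <<- FALSE; NULL})
        if (ok && all(is.finite(gc2))) {
          Jc <- numericalJacobian(gFull, cand, opt$jacRelStep)
          stc <- tryCatch(evalF(cand, lam, gc2, Jc),
                          error = function(e) NULL)
          if (!is.null(stc) && is.finite(stc$F) && stc$F >= st$F) {
            mf <- cand; gm <- gc2; J <- Jc; st <- stc
            lm <- lm / 10
            accepted <- TRUE
            break
          }
        }
      }
      lm <- max(lm * 10, 1e-6)
    }

    ## ---- lambda step (damped Newton) ----
    if (estH) {
      dl <- tryCatch(drop(solve(-st$hyp$hess, st$hyp$grad)),
                     error = function(e) NULL)
      if (!is.null(dl)) {
        step <- 1
        for (half in 1:8) {
          candL <- lam + step * dl
          stc <- tryCatch(evalF(mf, candL, gm, J), error = function(e) NULL)
          if (!is.null(stc) && is.finite(stc$F) && stc$F >= st$F) {
            lam <- candL; st <- stc
            break
          }
          step <- step / 2
        }
      }
    }

    trajectory <- c(trajectory, st$F)
    dF <- st$F - fStart
    nSmall <- if (dF < opt$tol) nSmall + 1L else 0L
    if (nSmall >= 2L) { converged <- TRUE; break }
  }

  ## embed free-subspace posterior into the full parameter space
  d <- length(prior@mean)
  mFull <- prior@mean; mFull[free] <- mf
  SFull <- matrix(0, d, d)
  SFull[free, free] <- st$Sf
  dimnames(SFull) <- list(names(prior@mean), names(prior@mean))
  theta <- new("GaussianBelief", mean = mFull, cov = SFull)
  lambda <- new("GaussianBelief", mean = lam, cov = st$Sl)

  bd <- laplaceFreeEnergy(st$e, st$Cy, n, eTheta = mf - muf, CTheta = Cf,
                          STheta = st$Sf,
                          eLambda = if (estH) lam - mul,
                          CLambda = if (estH) noise@hyperCov,
                          SLambda = if (estH) st$Sl,
                          regionMap = regionMap,
                          setMap = if (!is.null(setMap))
                            lapply(setMap, function(ix)
                              match(intersect(ix, free), free)))
  crit <- criterionSet(bd@fL, bd@accuracy, pf, n, withAicc = withAicc)
  new("FitResult", theta = theta, lambda = lambda, breakdown = bd,
      criteria = crit, iterations = iter, converged = converged,
      trajectory = trajectory,
      dataSignature = c(n, sum(y), sum(y^2)))
}
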