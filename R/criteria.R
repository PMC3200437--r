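## Evidence approximations: Laplace free energy with its accuracy/complexity
## decomposition, AIC/BIC/AICc, Bayes factors. All logs are natural logs.
## Log-determinants always go through the Cholesky factor, never det().

## Cholesky with a definite-ness error message; S may be a scalar/vector of
## variances (diagonal covariance) or a full matrix.
.cholPD <- function(S, what = "covariance") {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R) || any(diag(R) <= 0))
    stop(what, " matrix is not positive definite", call. = FALSE)
  R
}

.asCov <- function(C, n) {
  if (is.matrix(C)) {
    if (nrow(C) != n || ncol(C) != n)
      stop("covariance dimension does not match vector length", call. = FALSE)
    return(C)
  }
  diag(rep_len(as.numeric(C), n), nrow = n)
}

## quadratic form e' C^{-1} e and log|C| in one pass
.quadLogDet <- function(e, C, what = "covariance") {
  n <- length(e)
  if (!is.matrix(C)) {
    v <- rep_len(as.numeric(C), n)
    if (any(v <= 0)) stop(what, " matrix is not positive definite", call. = FALSE)
    return(list(quad = sum(e^2 / v), logdet = sum(log(v))))
  }
  if (nrow(C) != n) stop("dimension mismatch", call. = FALSE)
  R <- .cholPD(C, what)
  z <- backsolve(R, e, transpose = TRUE)
  list(quad = sum(z^2), logdet = 2 * sum(log(diag(R))))
}

#' Model accuracy term
#'
#' The data-fit part of the Laplace free energy for residuals \eqn{e_y} under
#' Gaussian noise with covariance \eqn{C_y}:
#' \deqn{\mathrm{Accuracy} = -\tfrac12 e_y^T C_y^{-1} e_y
#'   - \tfrac12 \log|C_y| - \tfrac{N}{2}\log 2\pi.}
#'
#' @param ey residual vector \eqn{y - g(m_\theta)}.
#' @param Cy noise covariance: a matrix, a vector of variances, or a single
#'   variance recycled over all points.
#' @param n number of data points; must equal \code{length(ey)}.
#' @return Accuracy in log-density units (a scalar).
#' @examples
#' evidenceAccuracy(0, 1, 1)            # -log(2*pi)/2
#' evidenceAccuracy(c(1, 1), diag(2), 2) # -1 - log(2*pi)
#' @export
evidenceAccuracy <- function(ey, Cy, n = length(ey)) {
  ey <- as.numeric(ey)
  if (length(ey) != n) stop("length(ey) must equal n", call. = FALSE)
  ql <- .quadLogDet(ey, Cy, "noise covariance")
  -0.5 * ql$quad - 0.5 * ql$logdet - n / 2 * log(2 * pi)
}

#' Model complexity terms
#'
#' The penalty part of the Laplace free energy: for parameters,
#' \deqn{\tfrac12 e_\theta^T C_\theta^{-1} e_\theta + \tfrac12\log|C_\theta|
#'   - \tfrac12\log|S_\theta|,}
#' where \eqn{e_\theta = m_\theta - \mu_\theta} is the posterior departure
#' from the prior mean and \eqn{\log|C_\theta|/|S_\theta|} is (twice) the
#' Occam factor. The analogous hyperparameter term is returned as zero when
#' the hyper arguments are absent (noise known).
#'
#' @param eTheta posterior-minus-prior mean deviation of the parameters.
#' @param CTheta,STheta prior and posterior covariance (matrix or variance
#'   vector/scalar).
#' @param eLambda,CLambda,SLambda optional hyperparameter counterparts.
#' @return Named numeric vector \code{c(params = ..., hypers = ...)}.
#' @examples
#' evidenceComplexity(0, 1, 1)    # posterior equals prior: zero
#' evidenceComplexity(1, 1, 1)    # 0.5
#' @export
evidenceComplexity <- function(eTheta, CTheta, STheta,
                               eLambda = NULL, CLambda = NULL,
                               SLambda = NULL) {
  eTheta <- as.numeric(eTheta)
  d <- length(eTheta)
  if (is.matrix(CTheta) && nrow(CTheta) != d)
    stop("CTheta dimension does not match eTheta", call. = FALSE)
  if (is.matrix(STheta) && nrow(STheta) != d)
    stop("STheta dimension does not match eTheta", call. = FALSE)
  qc <- .quadLogDet(eTheta, CTheta, "prior covariance")
  ls <- .quadLogDet(numeric(d), STheta, "posterior covariance")$logdet
  params <- 0.5 * qc$quad + 0.5 * qc$logdet - 0.5 * ls
  hypers <- 0
  if (!is.null(eLambda)) {
    eLambda <- as.numeric(eLambda)
    qh <- .quadLogDet(eLambda, CLambda, "hyper prior covariance")
    lh <- .quadLogDet(numeric(length(eLambda)), SLambda,
                      "hyper posterior covariance")$logdet
    hypers <- 0.5 * qh$quad + 0.5 * qh$logdet - 0.5 * lh
  }
  c(params = params, hypers = hypers)
}

.checkPartition <- function(map, size, what) {
  idx <- sort(unlist(map, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(size)))
    stop(what, " map must partition 1:", size, call. = FALSE)
}

.subCov <- function(C, idx, total) {
  if (is.matrix(C)) C[idx, idx, drop = FALSE]
  else rep_len(as.numeric(C), total)[idx]
}

#' Laplace free energy with accuracy/complexity breakdown
#'
#' Combines [evidenceAccuracy()] and [evidenceComplexity()] into
#' \eqn{F_L = \mathrm{Accuracy} - \mathrm{Complexity}} and optionally
#' decomposes the accuracy over regions (blocks of the data vector) and the
#' complexity over parameter sets. Per-region terms sum exactly to the total
#' when \eqn{C_y} has no cross-region covariance; the per-set complexity
#' ignores cross-set posterior correlation and is approximate (the exact
#' total is always stored).
#'
#' @inheritParams evidenceAccuracy
#' @inheritParams evidenceComplexity
#' @param regionMap optional named list of index vectors partitioning the
#'   data vector into regions.
#' @param setMap optional named list of index vectors partitioning the
#'   parameter vector into sets (e.g. input/intrinsic/modulatory).
#' @return An [EvidenceBreakdown-class].
#' @examples
#' laplaceFreeEnergy(ey = c(0, 0), Cy = 1, n = 2,
#'                   eTheta = 0, CTheta = 1, STheta = 1)
#' @export
laplaceFreeEnergy <- function(ey, Cy, n = length(ey), eTheta, CTheta, STheta,
                              eLambda = NULL, CLambda = NULL, SLambda = NULL,
                              regionMap = NULL, setMap = NULL) {
  ey <- as.numeric(ey); eTheta <- as.numeric(eTheta)
  acc <- evidenceAccuracy(ey, Cy, n)
  cx <- evidenceComplexity(eTheta, CTheta, STheta, eLambda, CLambda, SLambda)
  accBy <- setNames(numeric(0), character(0))
  if (!is.null(regionMap)) {
    .checkPartition(regionMap, n, "region")
    accBy <- vapply(regionMap, function(idx)
      evidenceAccuracy(ey[idx], .subCov(Cy, idx, n), length(idx)), 0)
  }
  cxBy <- setNames(numeric(0), character(0))
  if (!is.null(setMap)) {
    .checkPartition(setMap, length(eTheta), "parameter-set")
    cxBy <- vapply(setMap, function(idx)
      evidenceComplexity(eTheta[idx], .subCov(CTheta, idx, length(eTheta)),
                         .subCov(STheta, idx, length(eTheta)))[["params"]], 0)
  }
  new("EvidenceBreakdown", accuracy = acc,
      complexityParams = unname(cx[["params"]]),
      complexityHypers = unname(cx[["hypers"]]),
      fL = acc - cx[["params"]] - cx[["hypers"]],
      accuracyByRegion = accBy, complexityBySet = cxBy)
}

#' Akaike information criterion (evidence scale)
#'
#' \code{AIC = Accuracy - p}: every free parameter pays a unit penalty,
#' regardless of its prior. The accuracy is evaluated at the posterior means.
#'
#' @param accuracy accuracy term from [evidenceAccuracy()].
#' @param p number of free parameters.
#' @return AIC as a log-evidence approximation.
#' @export
aic <- function(accuracy, p) {
  if (p < 0) stop("p must be >= 0", call. = FALSE)
  accuracy - p
}

#' Bayesian information criterion (evidence scale)
#'
#' \code{BIC = Accuracy - (p/2) log N} (natural log).
#'
#' @inheritParams aic
#' @param n number of data points.
#' @return BIC as a log-evidence approximation.
#' @export
bic <- function(accuracy, p, n) {
  if (p < 0) stop("p must be >= 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  accuracy - p / 2 * log(n)
}

#' Corrected AIC (evidence scale)
#'
#' \code{AICc = AIC - p(p+1)/(N-p-1)}. Requires \eqn{N > p + 1}; below that
#' the correction changes sign and the criterion is not meaningful, so the
#' function errors rather than returning a value.
#'
#' @inheritParams bic
#' @return AICc as a log-evidence approximation.
#' @export
aicc <- function(accuracy, p, n) {
  if (p < 0) stop("p must be >= 0", call. = FALSE)
  if (n <= p + 1)
    stop("AICc requires n > p + 1 (got n = ", n, ", p = ", p, ")",
         call. = FALSE)
  aic(accuracy, p) - p * (p + 1) / (n - p - 1)
}

#' Bayes factor and posterior model probability
#'
#' Compares two models by their (approximate) log evidences. Works in logs
#' throughout; the posterior probability of model 1 under equal model priors
#' is \eqn{B_{12}/(1+B_{12})}, computed stably as the logistic of the log
#' Bayes factor. A Bayes factor of 20 (log Bayes factor 3) corresponds to a
#' posterior probability just above 0.95.
#'
#' @param logEv1,logEv2 log evidences of models 1 and 2.
#' @return List with \code{logBF}, \code{bf} (may overflow to \code{Inf} for
#'   huge log Bayes factors) and \code{posteriorProb1}.
#' @examples
#' bayesFactor(log(20), 0)$posteriorProb1  # > 0.95
#' @export
bayesFactor <- function(logEv1, logEv2) {
  logBF <- logEv1 - logEv2
  list(logBF = logBF, bf = exp(logBF), posteriorProb1 = plogis(logBF))
}

#' Assemble a CriterionSet
#'
#' @param fL Laplace free energy.
#' @param accuracy accuracy at the posterior means (penalised by AIC/BIC).
#' @param p free-parameter count.
#' @param n data-point count.
#' @param withAicc compute AICc too (requires \code{n > p + 1}).
#' @return A [CriterionSet-class].
#' @export
criterionSet <- function(fL, accuracy, p, n, withAicc = TRUE) {
  new("CriterionSet", fL = fL, aic = aic(accuracy, p),
      bic = bic(accuracy, p, n),
      aicc = if (withAicc) aicc(accuracy, p, n) else NA_real_,
      p = as.integer(p), n = as.integer(n))
}
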