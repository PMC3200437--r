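## Central S4 classes. All covariances are dense base matrices; positive
## SEMI-definiteness is the class contract (zero prior variance encodes a
## fixed parameter), strict definiteness is checked where inversion happens.

.symTol <- 1e-8

.isSymmetricPSD <- function(S, tol = .symTol) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) return("not a square matrix")
  if (!all(is.finite(S))) return("contains non-finite entries")
  sc <- max(abs(S), 1)
  if (max(abs(S - t(S))) > tol * sc) return("not symmetric within tolerance")
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * sc) return("not positive semi-definite")
  TRUE
}

#' Gaussian belief over a parameter vector
#'
#' A mean vector with covariance matrix, representing a prior \eqn{p(\theta|m)},
#' an approximate posterior \eqn{q(\theta|y,m)}, or a belief over noise
#' log-precisions \eqn{\lambda}. Covariances must be symmetric positive
#' semi-definite; a zero variance on a coordinate marks that parameter as
#' fixed (not estimated).
#'
#' @slot mean numeric vector of length \eqn{d}.
#' @slot cov \eqn{d \times d} symmetric positive semi-definite matrix.
#' @export
setClass("GaussianBelief",
  representation(mean = "numeric", cov = "matrix"))

setValidity("GaussianBelief", function(object) {
  d <- length(object@mean)
  if (d < 1) return("mean must have length >= 1")
  if (!all(is.finite(object@mean))) return("mean has non-finite entries")
  if (nrow(object@cov) != d || ncol(object@cov) != d)
    return("cov dimensions do not match mean length")
  .isSymmetricPSD(object@cov)
})

#' Construct a GaussianBelief
#'
#' @param mean numeric mean vector.
#' @param cov covariance matrix, or a numeric vector of variances (expanded
#'   to a diagonal matrix), or a single variance recycled over all
#'   coordinates.
#' @return A [GaussianBelief-class] object.
#' @examples
#' gaussianBelief(c(0, 0), diag(2))
#' gaussianBelief(0, 6.05^2)
#' @export
gaussianBelief <- function(mean, cov) {
  nm <- names(mean)
  mean <- as.numeric(mean)
  names(mean) <- nm
  if (!is.matrix(cov)) {
    v <- rep_len(as.numeric(cov), length(mean))
    cov <- diag(v, nrow = length(mean))
  }
  new("GaussianBelief", mean = mean, cov = cov)
}

#' Free-energy breakdown into accuracy and complexity
#'
#' Holds the Laplace free energy \eqn{F_L = } accuracy \eqn{-} parameter
#' complexity \eqn{-} hyperparameter complexity, together with optional
#' per-region accuracy terms and per-parameter-set complexity terms. The
#' per-set decomposition ignores cross-set posterior correlation and is
#' therefore approximate; the exact totals are always stored alongside.
#'
#' @slot accuracy data-fit term, log-density units.
#' @slot complexityParams parameter complexity (may be negative).
#' @slot complexityHypers hyperparameter complexity; zero when the noise
#'   hyperparameters are known.
#' @slot fL the Laplace free energy.
#' @slot accuracyByRegion named numeric, per-region accuracy (sums to
#'   \code{accuracy} when noise is block-independent across regions).
#' @slot complexityBySet named numeric, approximate per-set complexity.
#' @export
setClass("EvidenceBreakdown",
  representation(accuracy = "numeric", complexityParams = "numeric",
                 complexityHypers = "numeric", fL = "numeric",
                 accuracyByRegion = "numeric", complexityBySet = "numeric"))

setValidity("EvidenceBreakdown", function(object) {
  for (s in c("accuracy", "complexityParams", "complexityHypers", "fL"))
    if (length(slot(object, s)) != 1 || !is.finite(slot(object, s)))
      return(sprintf("%s must be a finite scalar", s))
  resid <- object@fL -
    (object@accuracy - object@complexityParams - object@complexityHypers)
  if (abs(resid) > 1e-10 * max(1, abs(object@fL)))
    return("fL must equal accuracy - complexityParams - complexityHypers")
  TRUE
})

#' Log-evidence approximations for one fitted model
#'
#' The Laplace free energy together with AIC, BIC and AICc for the same fit,
#' plus the free-parameter count \eqn{p} and data-point count \eqn{N} used in
#' the penalties. \code{aicc} is \code{NA} when it was not requested.
#'
#' @slot fL,aic,bic,aicc log-evidence approximations (natural log).
#' @slot p integer free-parameter count (parameters with nonzero prior
#'   variance; hyperparameters are not counted).
#' @slot n integer number of data points.
#' @export
setClass("CriterionSet",
  representation(fL = "numeric", aic = "numeric", bic = "numeric",
                 aicc = "numeric", p = "integer", n = "integer"))

setValidity("CriterionSet", function(object) {
  if (object@p < 0L) return("p must be >= 0")
  if (object@n < 1L) return("n must be >= 1")
  TRUE
})

#' Bayesian GLM specification
#'
#' Design matrix plus isotropic Gaussian prior and known isotropic Gaussian
#' noise: \eqn{C_\theta = \sigma_p^2 I_p}, \eqn{C_y = \sigma_e^2 I_N},
#' prior mean \eqn{\mu_\theta} (default zero).
#'
#' @slot design \eqn{N \times p} design matrix.
#' @slot priorMean length-\eqn{p} prior mean of the regression coefficients.
#' @slot priorSd prior standard deviation \eqn{\sigma_p}.
#' @slot noiseSd observation noise standard deviation \eqn{\sigma_e}.
#' @export
setClass("GLMSpec",
  representation(design = "matrix", priorMean = "numeric",
                 priorSd = "numeric", noiseSd = "numeric"))

setValidity("GLMSpec", function(object) {
  if (nrow(object@design) < 1 || ncol(object@design) < 1)
    return("design must be at least 1 x 1")
  if (!all(is.finite(object@design))) return("design has non-finite entries")
  if (length(object@priorMean) != ncol(object@design))
    return("priorMean length must equal ncol(design)")
  if (length(object@priorSd) != 1 || object@priorSd <= 0)
    return("priorSd must be a positive scalar")
  if (length(object@noiseSd) != 1 || object@noiseSd <= 0)
    return("noiseSd must be a positive scalar")
  TRUE
})

#' Construct a GLMSpec
#'
#' @param design numeric design matrix (\eqn{N \times p}).
#' @param priorSd prior SD \eqn{\sigma_p} of the regression coefficients.
#' @param noiseSd known noise SD \eqn{\sigma_e}.
#' @param priorMean prior mean vector; default all zero.
#' @return A [GLMSpec-class]. Warns if the design is column-rank deficient.
#' @examples
#' glmSpec(cbind(1, 1:10), priorSd = 6.05, noiseSd = 1)
#' @export
glmSpec <- function(design, priorSd, noiseSd, priorMean = 0) {
  design <- as.matrix(design)
  priorMean <- rep_len(as.numeric(priorMean), ncol(design))
  sp <- new("GLMSpec", design = design, priorMean = priorMean,
            priorSd = as.numeric(priorSd), noiseSd = as.numeric(noiseSd))
  if (qr(design)$rank < ncol(design))
    warning("design matrix is column-rank deficient")
  sp
}

#' Bilinear DCM structure and prior hyperparameters
#'
#' Structural masks for the intrinsic (\eqn{A}), modulatory (\eqn{B^j}) and
#' input (\eqn{C}) connections of a multi-region network, the prior SDs of
#' each connection class, the noise hyper-prior, and the sampling geometry.
#' Self-connections are always present (diagonal of \code{aMask} all ones)
#' and carry the stabilising prior \eqn{N(-1, \sigma_{self}^2)}.
#'
#' @slot nRegions number of regions.
#' @slot aMask binary regions x regions matrix; entry (i,k) = 1 when the
#'   connection from region k to region i is free.
#' @slot bMasks list (one per input) of binary regions x regions matrices.
#' @slot cMask binary regions x inputs matrix.
#' @slot sigmaSelf,sigmaCross,sigmaS prior SDs for self, cross, and
#'   modulatory/input connections (defaults 0.177, 0.5, 2).
#' @slot hyperMean,hyperVar prior mean and variance of the per-region noise
#'   log-precision (defaults 0 and 1, i.e. mean prior precision ~1.7).
#' @slot TR sampling interval in seconds.
#' @slot nScans number of scans per region.
#' @slot regionLabels,inputLabels character labels.
#' @export
setClass("DCMSpec",
  representation(nRegions = "integer", aMask = "matrix", bMasks = "list",
                 cMask = "matrix", sigmaSelf = "numeric",
                 sigmaCross = "numeric", sigmaS = "numeric",
                 hyperMean = "numeric", hyperVar = "numeric",
                 TR = "numeric", nScans = "integer",
                 regionLabels = "character", inputLabels = "character"))

setValidity("DCMSpec", function(object) {
  r <- object@nRegions
  if (r < 1L) return("nRegions must be >= 1")
  if (!identical(dim(object@aMask), c(r, r)))
    return("aMask must be nRegions x nRegions")
  if (any(diag(object@aMask) != 1))
    return("self-connections must always be present (diag(aMask) == 1)")
  if (!all(object@aMask %in% c(0, 1))) return("aMask must be binary")
  nin <- ncol(object@cMask)
  if (nrow(object@cMask) != r) return("cMask must have nRegions rows")
  if (length(object@bMasks) != nin)
    return("bMasks must have one matrix per input")
  for (bm in object@bMasks) {
    if (!identical(dim(bm), c(r, r))) return("each bMask must be r x r")
    if (!all(bm %in% c(0, 1))) return("bMasks must be binary")
  }
  if (!all(object@cMask %in% c(0, 1))) return("cMask must be binary")
  if (object@TR <= 0) return("TR must be positive")
  if (object@nScans < 1L) return("nScans must be >= 1")
  if (length(object@regionLabels) != r)
    return("regionLabels length must equal nRegions")
  if (length(object@inputLabels) != nin)
    return("inputLabels length must equal the number of inputs")
  TRUE
})

#' Construct a DCMSpec
#'
#' @param aMask,bMasks,cMask structural masks (see [DCMSpec-class]).
#' @param TR sampling interval in seconds.
#' @param nScans number of scans.
#' @param regionLabels,inputLabels optional labels.
#' @param sigmaSelf,sigmaCross,sigmaS,hyperMean,hyperVar prior
#'   hyperparameters; defaults are the standard DCM-for-fMRI values.
#' @return A [DCMSpec-class].
#' @export
dcmSpec <- function(aMask, bMasks, cMask, TR, nScans,
                    regionLabels = NULL, inputLabels = NULL,
                    sigmaSelf = 0.177, sigmaCross = 0.5, sigmaS = 2,
                    hyperMean = 0, hyperVar = 1) {
  aMask <- as.matrix(aMask); cMask <- as.matrix(cMask)
  r <- nrow(aMask)
  if (is.null(regionLabels)) regionLabels <- paste0("R", seq_len(r))
  if (is.null(inputLabels)) inputLabels <- paste0("u", seq_len(ncol(cMask)))
  new("DCMSpec", nRegions = as.integer(r), aMask = aMask,
      bMasks = lapply(bMasks, as.matrix), cMask = cMask,
      sigmaSelf = sigmaSelf, sigmaCross = sigmaCross, sigmaS = sigmaS,
      hyperMean = hyperMean, hyperVar = hyperVar,
      TR = as.numeric(TR), nScans = as.integer(nScans),
      regionLabels = regionLabels, inputLabels = inputLabels)
}

#' Parameter values of a bilinear DCM
#'
#' Connection strengths in Hz and per-region hemodynamic parameters on their
#' natural scale. Entries are exactly zero wherever the corresponding mask in
#' the [DCMSpec-class] is zero.
#'
#' @slot A intrinsic connection matrix (Hz).
#' @slot B list of modulatory matrices, one per input (Hz).
#' @slot C input connection matrix (Hz).
#' @slot h regions x 6 matrix with columns \code{kappa} (signal decay, 1/s),
#'   \code{gamma} (autoregulation, 1/s), \code{tau} (mean transit time, s),
#'   \code{alpha} (vessel stiffness), \code{E0} (resting oxygen extraction)
#'   and \code{epsilon} (intra/extravascular signal ratio).
#' @export
setClass("DCMParams",
  representation(A = "matrix", B = "list", C = "matrix", h = "matrix"))

.hColumns <- c("kappa", "gamma", "tau", "alpha", "E0", "epsilon")

setValidity("DCMParams", function(object) {
  r <- nrow(object@A)
  if (ncol(object@A) != r) return("A must be square")
  if (nrow(object@C) != r) return("C must have one row per region")
  for (b in object@B)
    if (!identical(dim(b), dim(object@A))) return("B matrices must match A")
  if (!identical(colnames(object@h), .hColumns))
    return(paste("h columns must be", paste(.hColumns, collapse = ", ")))
  if (nrow(object@h) != r) return("h must have one row per region")
  if (any(!is.finite(object@A)) || any(!is.finite(object@h)))
    return("non-finite parameter values")
  TRUE
})

#' Multi-region BOLD time series
#'
#' @slot values nScans x nRegions matrix of BOLD signal (arbitrary units).
#' @slot TR sampling interval in seconds.
#' @slot regionLabels character labels, one per column.
#' @export
setClass("RegionTimeseries",
  representation(values = "matrix", TR = "numeric",
                 regionLabels = "character"))

setValidity("RegionTimeseries", function(object) {
  if (!all(is.finite(object@values))) return("values must be finite")
  if (length(object@regionLabels) != ncol(object@values))
    return("one label per region required")
  if (object@TR <= 0) return("TR must be positive")
  TRUE
})

#' Experimental inputs on a fine time grid
#'
#' @slot u fine-grid steps x nInputs matrix of input values.
#' @slot dt fine-grid step in seconds (must divide the scan TR).
#' @slot labels input labels (e.g. \code{u_aud}, \code{u_int}).
#' @export
setClass("InputSet",
  representation(u = "matrix", dt = "numeric", labels = "character"))

setValidity("InputSet", function(object) {
  if (!all(is.finite(object@u))) return("u must be finite")
  if (object@dt <= 0) return("dt must be positive")
  if (length(object@labels) != ncol(object@u))
    return("one label per input required")
  TRUE
})

#' Signal-to-noise calibration
#'
#' Encodes SNR = \eqn{\langle\sigma_y\rangle / \sigma_e}: the mean temporal
#' standard deviation of the noiseless signal divided by the noise SD.
#'
#' @slot targetSnr target SNR.
#' @slot signalSd mean signal SD \eqn{\langle\sigma_y\rangle}.
#' @slot noiseSd implied noise SD \eqn{\sigma_e}.
#' @export
setClass("SNRSpec",
  representation(targetSnr = "numeric", signalSd = "numeric",
                 noiseSd = "numeric"))

setValidity("SNRSpec", function(object) {
  if (object@targetSnr <= 0 || object@signalSd <= 0 || object@noiseSd <= 0)
    return("all SNRSpec fields must be positive")
  if (abs(object@targetSnr - object@signalSd / object@noiseSd) >
      1e-8 * object@targetSnr)
    return("targetSnr must equal signalSd / noiseSd")
  TRUE
})

#' Precision-basis noise model
#'
#' Observation noise with inverse covariance
#' \eqn{C_y^{-1} = \sum_i \exp(\lambda_i) Q_i} and Gaussian prior on the
#' log-precisions \eqn{\lambda}. Each basis \eqn{Q_i} is either a full
#' positive semi-definite matrix or, for the common independent-blocks case,
#' an integer index vector meaning identity on those data points.
#'
#' @slot bases list of precision bases (matrices or integer index vectors).
#' @slot hyperMean,hyperCov prior mean vector and covariance of
#'   \eqn{\lambda}.
#' @slot n total number of data points.
#' @export
setClass("NoiseModel",
  representation(bases = "list", hyperMean = "numeric",
                 hyperCov = "matrix", n = "integer"))

setValidity("NoiseModel", function(object) {
  k <- length(object@bases)
  if (k < 1) return("at least one precision basis required")
  if (length(object@hyperMean) != k) return("hyperMean length must match bases")
  if (!identical(dim(object@hyperCov), c(k, k)))
    return("hyperCov must be k x k")
  for (q in object@bases) {
    if (is.matrix(q)) {
      msg <- .isSymmetricPSD(q)
      if (!isTRUE(msg)) return(paste("basis:", msg))
      if (nrow(q) != object@n) return("matrix basis dimension must equal n")
    } else {
      idx <- as.integer(q)
      if (any(idx < 1L) || any(idx > object@n)) return("basis index out of range")
    }
  }
  TRUE
})

#' Construct a NoiseModel
#'
#' @param bases list of precision bases; integer vectors denote identity
#'   blocks on those indices.
#' @param n total number of data points.
#' @param hyperMean,hyperCov prior on the log-precisions; \code{hyperCov}
#'   may be given as a vector of variances.
#' @return A [NoiseModel-class].
#' @export
noiseModel <- function(bases, n, hyperMean = 0, hyperCov = 1) {
  k <- length(bases)
  hyperMean <- rep_len(as.numeric(hyperMean), k)
  if (!is.matrix(hyperCov))
    hyperCov <- diag(rep_len(as.numeric(hyperCov), k), nrow = k)
  new("NoiseModel", bases = bases, hyperMean = hyperMean,
      hyperCov = hyperCov, n = as.integer(n))
}

#' Per-region i.i.d. noise model
#'
#' The standard DCM-for-fMRI noise model: one identity precision basis per
#' region on the concatenated data vector, prior \eqn{\lambda_i \sim N(0,1)}
#' (mean prior precision \eqn{\exp(0.5) \approx 1.7}).
#'
#' @param nScans scans per region.
#' @param nRegions number of regions.
#' @param hyperMean,hyperVar prior mean and variance of each log-precision.
#' @return A [NoiseModel-class] over \code{nScans * nRegions} points.
#' @export
regionNoiseModel <- function(nScans, nRegions, hyperMean = 0, hyperVar = 1) {
  bases <- lapply(seq_len(nRegions), function(r)
    seq.int((r - 1L) * nScans + 1L, r * nScans))
  noiseModel(bases, n = nScans * nRegions,
             hyperMean = rep(hyperMean, nRegions),
             hyperCov = rep(hyperVar, nRegions))
}

#' Result of a variational Laplace fit
#'
#' @slot theta posterior [GaussianBelief-class] over parameters.
#' @slot lambda posterior [GaussianBelief-class] over noise log-precisions
#'   (a degenerate point belief when the noise was known).
#' @slot breakdown [EvidenceBreakdown-class] at the final beliefs.
#' @slot criteria [CriterionSet-class] for the fit.
#' @slot iterations number of accepted iterations.
#' @slot converged logical convergence flag.
#' @slot trajectory free energy after each accepted step.
#' @slot dataSignature c(n, sum, sum of squares) of the fitted data vector,
#'   used to verify that two fits refer to the same data.
#' @export
setClass("FitResult",
  representation(theta = "GaussianBelief", lambda = "GaussianBelief",
                 breakdown = "EvidenceBreakdown", criteria = "CriterionSet",
                 iterations = "integer", converged = "logical",
                 trajectory = "numeric", dataSignature = "numeric"))

#' Aggregated sweep over SNR or sample size
#'
#' One row per (grid point x criterion): the aggregated oriented log Bayes
#' factor (true model versus the alternative), its SD and central 90%
#' interval over replications, and bookkeeping (replications, exclusions,
#' generating model, master seed).
#'
#' @slot table data.frame of results.
#' @slot axis "SNR" or "N".
#' @slot aggregator "mean" or "median".
#' @slot reps replications per grid point.
#' @slot seed master seed.
#' @slot trueModel "full" or "nested".
#' @export
setClass("SweepResult",
  representation(table = "data.frame", axis = "character",
                 aggregator = "character", reps = "integer",
                 seed = "integer", trueModel = "character"))

setValidity("SweepResult", function(object) {
  if (object@reps < 1L) return("reps must be positive")
  if (!object@axis %in% c("SNR", "N")) return("axis must be SNR or N")
  if (!object@aggregator %in% c("mean", "median"))
    return("aggregator must be mean or median")
  TRUE
})
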