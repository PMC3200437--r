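## Synthetic-data generators: event-related GLM design matrices built from a
## canonical double-gamma HRF basis, SNR calibration, and prior-drawn GLM and
## DCM data sets. Everything is seeded and reconstructible.

## canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6) with a
## dispersion scale, evaluated at times t (seconds)
.hrfShape <- function(t, disp = 1) {
  dgamma(t, shape = 6 / disp, rate = 1 / disp) -
    dgamma(t, shape = 16 / disp, rate = 1 / disp) / 6
}

#' Canonical HRF basis set
#'
#' The canonical double-gamma hemodynamic response together with its
#' temporal derivative (finite difference over a 0.1 s onset shift) and
#' dispersion derivative (finite difference over a 1% dispersion change),
#' evaluated on a time grid. Each column is scaled to unit peak absolute
#' value.
#'
#' @param t time grid in seconds.
#' @param nBasis number of basis functions (1 to 3).
#' @return Matrix with \code{nBasis} columns.
#' @export
hrfBasis <- function(t, nBasis = 3) {
  stopifnot(nBasis >= 1, nBasis <= 3)
  b <- cbind(.hrfShape(t))
  if (nBasis >= 2) b <- cbind(b, (.hrfShape(t - 0.1) - .hrfShape(t)) / 0.1)
  if (nBasis >= 3) b <- cbind(b, (.hrfShape(t) - .hrfShape(t, 1.01)) / 0.01)
  apply(b, 2, function(col) col / max(abs(col)))
}

#' Event-related GLM design matrix
#'
#' Emulates a multi-condition event-related fMRI design: per-condition event
#' onsets are convolved with the canonical HRF basis (canonical + temporal +
#' dispersion derivatives) and sampled at the scan times. Columns are
#' ordered condition-major (all basis functions of condition 1, then
#' condition 2, ...), so the nested design is the full design with the first
#' condition's columns removed.
#'
#' @param nScans number of scans (rows).
#' @param conditions number of event conditions.
#' @param basisPerCondition basis functions per condition (1 to 3).
#' @param TR repetition time in seconds.
#' @param meanIsi mean inter-trial interval in seconds for the pseudo-random
#'   schedule (onsets jittered uniformly by +/- 25%).
#' @param schedule optional data.frame with columns \code{onset} (s) and
#'   \code{condition} overriding the generated schedule; zero rows give a
#'   zero design matrix.
#' @param seed optional integer seed for the schedule.
#' @return \code{nScans x (conditions * basisPerCondition)} design matrix
#'   with an attached \code{"schedule"} attribute.
#' @examples
#' dim(makeGlmDesign(seed = 1))  # 351 x 12
#' @export
makeGlmDesign <- function(nScans = 351, conditions = 4,
                          basisPerCondition = 3, TR = 2, meanIsi = 8,
                          schedule = NULL, seed = NULL) {
  stopifnot(conditions * basisPerCondition >= 1)
  duration <- nScans * TR
  if (is.null(schedule)) {
    if (!is.null(seed)) set.seed(seed)
    onsets <- numeric(0)
    t0 <- 0
    repeat {
      t0 <- t0 + stats::runif(1, 0.75 * meanIsi, 1.25 * meanIsi)
      if (t0 >= duration - 1) break
      onsets <- c(onsets, t0)
    }
    ## balanced pseudo-random condition assignment, block-permuted
    cond <- integer(length(onsets))
    i <- 1L
    while (i <= length(onsets)) {
      blk <- sample(conditions)
      take <- min(conditions, length(onsets) - i + 1L)
      cond[i:(i + take - 1L)] <- blk[seq_len(take)]
      i <- i + take
    }
    schedule <- data.frame(onset = onsets, condition = cond)
  } else {
    if (nrow(schedule) && any(schedule$onset >= duration))
      stop("event schedule exceeds scan duration", call. = FALSE)
  }
  dtf <- 0.1
  nFine <- ceiling(duration / dtf) + 1L
  basis <- hrfBasis(seq(0, 32, by = dtf), basisPerCondition)
  scanIdx <- round((seq_len(nScans) - 1) * TR / dtf) + 1L
  X <- matrix(0, nScans, conditions * basisPerCondition)
  for (cd in seq_len(conditions)) {
    stick <- numeric(nFine)
    ons <- schedule$onset[schedule$condition == cd]
    if (length(ons)) stick[round(ons / dtf) + 1L] <- 1
    for (b in seq_len(basisPerCondition)) {
      conv <- convolve(stick, rev(basis[, b]), type = "open")[seq_len(nFine)]
      X[, (cd - 1L) * basisPerCondition + b] <- conv[scanIdx]
    }
  }
  colnames(X) <- as.vector(outer(seq_len(basisPerCondition),
                                 seq_len(conditions),
                                 function(b, cd) sprintf("c%d.b%d", cd, b)))
  attr(X, "schedule") <- schedule
  X
}

#' Calibrate noise SD to a target SNR
#'
#' SNR is the mean temporal standard deviation of the noiseless signal(s)
#' divided by the noise SD. Given one or more signal vectors (prior-drawn
#' predictions for the GLM arm; per-region predictions for the DCM arm),
#' sets \eqn{\sigma_e = \langle\sigma_y\rangle / \mathrm{SNR}}.
#'
#' @param predictions numeric vector or matrix (one signal per column).
#' @param targetSnr target SNR (> 0).
#' @return An [SNRSpec-class].
#' @examples
#' calibrateSnr(cbind(sin(1:100)), targetSnr = 0.5)
#' @export
calibrateSnr <- function(predictions, targetSnr) {
  stopifnot(targetSnr > 0)
  predictions <- as.matrix(predictions)
  sds <- apply(predictions, 2, sd)
  sigY <- mean(sds)
  if (!is.finite(sigY) || sigY <= 0)
    stop("all signals are constant; SNR is undefined", call. = FALSE)
  new("SNRSpec", targetSnr = targetSnr, signalSd = sigY,
      noiseSd = sigY / targetSnr)
}

#' Prior-predictive signal draws for a GLM design
#'
#' Draws coefficient vectors from the prior \eqn{N(0, \sigma_p^2 I)} and
#' returns the noiseless predictions \eqn{X\theta}, used to estimate
#' \eqn{\langle\sigma_y\rangle} for SNR calibration.
#'
#' @param design design matrix.
#' @param sigmaP prior SD of the coefficients.
#' @param nDraws number of prior draws (default 1000).
#' @param seed optional integer seed.
#' @return \code{nrow(design) x nDraws} matrix of signals.
#' @export
glmPriorSignals <- function(design, sigmaP, nDraws = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- matrix(rnorm(ncol(design) * nDraws, 0, sigmaP), ncol(design))
  design %*% theta
}

#' Generate one synthetic GLM data set
#'
#' Coefficients are drawn from the prior, \eqn{\theta \sim N(0,\sigma_p^2 I)},
#' and data as \eqn{y = X\theta + e}, \eqn{e \sim N(0, \sigma_e^2 I)} with
#' \eqn{\sigma_e} taken from the SNR calibration.
#'
#' @param design design matrix.
#' @param sigmaP prior SD of the coefficients.
#' @param snrSpec an [SNRSpec-class] (from [calibrateSnr()]).
#' @param seed optional integer seed.
#' @return List with \code{y}, \code{theta} (true coefficients) and
#'   \code{noiseSd}.
#' @export
generateGlmDataset <- function(design, sigmaP, snrSpec, seed = NULL) {
  stopifnot(is(snrSpec, "SNRSpec"))
  if (!is.null(seed)) set.seed(seed)
  theta <- rnorm(ncol(design), 0, sigmaP)
  y <- drop(design %*% theta) +
    rnorm(nrow(design), 0, snrSpec@noiseSd)
  list(y = y, theta = theta, noiseSd = snrSpec@noiseSd)
}

#' Held-constant DCM parameters for the speech network
#'
#' The non-modulatory parameter values used when generating synthetic
#' speech-network data: self-connections -1 Hz, cross connections 0.3 Hz,
#' driving input 0.3 Hz, hemodynamics at their prior means. Modulatory
#' matrices are zero here; the generator fills them with prior draws.
#'
#' @param spec a speech-model [DCMSpec-class].
#' @param aCross cross-connection strength (Hz).
#' @param cIn driving-input strength (Hz).
#' @return A [DCMParams-class].
#' @export
speechFixedParams <- function(spec, aCross = 0.3, cIn = 0.3) {
  r <- spec@nRegions
  A <- matrix(aCross, r, r) * spec@aMask
  diag(A) <- -1
  C <- cIn * spec@cMask
  B <- lapply(spec@bMasks, function(m) matrix(0, r, r))
  dcmParams(A, B, C)
}

#' Generate one synthetic DCM data set
#'
#' Modulatory parameters are drawn from their shrinkage prior
#' \eqn{N(0, \sigma_s^2)} and made positive by taking absolute values
#' (facilitating modulation); all other parameters are held at
#' \code{fixedParams}. The noiseless prediction is integrated, the noise SD
#' is set so that the mean per-region temporal signal SD over noise SD
#' equals \code{snr}, and i.i.d. Gaussian noise is added per region.
#' Unstable draws (diverging neurodynamics) are resampled and counted.
#'
#' @param spec a [DCMSpec-class] from [buildSpeechModels()] (the nested spec
#'   has no \eqn{b_{AP}} entry, so its draw is exactly zero there).
#' @param snr target SNR.
#' @param fixedParams non-modulatory parameter values; default
#'   [speechFixedParams()].
#' @param inputs optional [InputSet-class]; default [makeSpeechInputs()].
#' @param seed optional integer seed.
#' @param maxResample resampling budget for unstable draws.
#' @return List with \code{ts} (noisy [RegionTimeseries-class]), \code{y}
#'   (concatenated data vector), \code{params} (true [DCMParams-class]),
#'   \code{snrSpec}, \code{inputs} and \code{resamples}.
#' @export
generateDcmDataset <- function(spec, snr, fixedParams = NULL, inputs = NULL,
                               seed = NULL, maxResample = 20L) {
  stopifnot(is(spec, "DCMSpec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fixedParams)) fixedParams <- speechFixedParams(spec)
  if (is.null(inputs)) inputs <- makeSpeechInputs(spec)
  resamples <- 0L
  repeat {
    params <- fixedParams
    params@B <- lapply(spec@bMasks, function(m) {
      b <- matrix(0, nrow(m), ncol(m))
      idx <- which(m == 1)
      if (length(idx)) b[idx] <- abs(rnorm(length(idx), 0, spec@sigmaS))
      b
    })
    pred <- tryCatch(dcmPredict(params, spec, inputs),
                     error = function(e) NULL)
    if (!is.null(pred)) break
    resamples <- resamples + 1L
    if (resamples > maxResample)
      stop("exceeded resampling budget for unstable parameter draws",
           call. = FALSE)
  }
  snrSpec <- calibrateSnr(pred@values, snr)
  noisy <- pred@values +
    matrix(rnorm(length(pred@values), 0, snrSpec@noiseSd),
           nrow(pred@values))
  ts <- new("RegionTimeseries", values = noisy, TR = spec@TR,
            regionLabels = spec@regionLabels)
  list(ts = ts, y = as.vector(noisy), params = params, snrSpec = snrSpec,
       inputs = inputs, resamples = resamples)
}
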