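## Bilinear DCM generative model: priors, parameter packing, neurodynamic and
## hemodynamic integration, and the two speech-network model structures.

## Natural-scale prior means of the hemodynamic parameters; kappa, tau and
## epsilon carry free Gaussian latents (value = mean * exp(latent)), the
## rest are fixed at their canonical values.
.hPriorMeans <- c(kappa = 0.64, gamma = 0.32, tau = 2, alpha = 0.32,
                  E0 = 0.4, epsilon = 1)
.hFree <- c("kappa", "tau", "epsilon")
.hLatentVar <- 1 / 256

#' Construct a DCMParams object
#'
#' @param A intrinsic connection matrix (Hz).
#' @param B list of modulatory matrices, one per input.
#' @param C input connection matrix.
#' @param h regions x 6 hemodynamic parameter matrix (natural scale); if
#'   omitted, every region gets the prior-mean hemodynamics.
#' @return A [DCMParams-class].
#' @export
dcmParams <- function(A, B, C, h = NULL) {
  A <- as.matrix(A)
  if (is.null(h))
    h <- matrix(.hPriorMeans, nrow(A), 6, byrow = TRUE,
                dimnames = list(NULL, .hColumns))
  ## Class must be named: a bare `C =` would partially match new()'s Class
  new(Class = "DCMParams", A = A, B = lapply(B, as.matrix),
      C = as.matrix(C), h = h)
}

## ---- parameter packing --------------------------------------------------
## The free parameter vector theta concatenates, in this fixed order:
## mask-present A entries (column-major), mask-present B entries per input,
## mask-present C entries, then 3 hemodynamic latents (kappa, tau, epsilon)
## per region. Masked entries never enter the vector.

.packLayout <- function(spec) {
  r <- spec@nRegions
  nin <- ncol(spec@cMask)
  aIdx <- which(spec@aMask == 1)
  bIdx <- lapply(spec@bMasks, function(m) which(m == 1))
  cIdx <- which(spec@cMask == 1)
  nA <- length(aIdx); nB <- sum(lengths(bIdx)); nC <- length(cIdx)
  nH <- 3L * r
  labA <- sprintf("a_%s%s", spec@regionLabels[row(spec@aMask)[aIdx]],
                  spec@regionLabels[col(spec@aMask)[aIdx]])
  labB <- unlist(lapply(seq_len(nin), function(j) {
    idx <- bIdx[[j]]
    if (!length(idx)) return(character(0))
    m <- spec@bMasks[[j]]
    sprintf("b%d_%s%s", j, spec@regionLabels[row(m)[idx]],
            spec@regionLabels[col(m)[idx]])
  }))
  labC <- sprintf("c_%s.%s", spec@regionLabels[row(spec@cMask)[cIdx]],
                  spec@inputLabels[col(spec@cMask)[cIdx]])
  labH <- as.vector(outer(.hFree, spec@regionLabels,
                          function(a, b) paste0("h_", a, "_", b)))
  list(aIdx = aIdx, bIdx = bIdx, cIdx = cIdx,
       nA = nA, nB = nB, nC = nC, nH = nH,
       names = c(labA, labB, labC, labH),
       sets = list(
         intrinsic = seq_len(nA),
         modulatory = if (nB) nA + seq_len(nB) else integer(0),
         input = if (nC) nA + nB + seq_len(nC) else integer(0),
         hemodynamic = nA + nB + nC + seq_len(nH)))
}

#' Prior belief over the packed DCM parameter vector
#'
#' Self-connections \eqn{A_{ii} \sim N(-1, \sigma_{self}^2)}, free cross
#' connections \eqn{A_{ik} \sim N(1/64, \sigma_{cross}^2)}, free modulatory
#' and input connections \eqn{\sim N(0, \sigma_s^2)}, and the hemodynamic
#' latents \eqn{\sim N(0, 1/256)}.
#'
#' @param spec a [DCMSpec-class].
#' @return A [GaussianBelief-class] with named mean vector.
#' @export
dcmPriorBelief <- function(spec) {
  lay <- .packLayout(spec)
  r <- spec@nRegions
  diagPos <- which(row(spec@aMask)[lay$aIdx] == col(spec@aMask)[lay$aIdx])
  mA <- rep(1 / 64, lay$nA); vA <- rep(spec@sigmaCross^2, lay$nA)
  mA[diagPos] <- -1; vA[diagPos] <- spec@sigmaSelf^2
  mean <- c(mA, rep(0, lay$nB), rep(0, lay$nC), rep(0, lay$nH))
  v <- c(vA, rep(spec@sigmaS^2, lay$nB), rep(spec@sigmaS^2, lay$nC),
         rep(.hLatentVar, lay$nH))
  names(mean) <- lay$names
  gaussianBelief(mean, v)
}

#' Unpack a parameter vector into DCMParams
#'
#' @param theta packed parameter vector (see [dcmPriorBelief()] for the
#'   layout).
#' @param spec the [DCMSpec-class] that defines the masks.
#' @return A [DCMParams-class] with masked entries exactly zero and
#'   hemodynamic latents mapped to the natural scale.
#' @export
dcmUnpack <- function(theta, spec) {
  lay <- .packLayout(spec)
  r <- spec@nRegions
  stopifnot(length(theta) == lay$nA + lay$nB + lay$nC + lay$nH)
  A <- matrix(0, r, r); A[lay$aIdx] <- theta[seq_len(lay$nA)]
  off <- lay$nA
  B <- vector("list", length(spec@bMasks))
  for (j in seq_along(B)) {
    Bj <- matrix(0, r, r)
    nj <- length(lay$bIdx[[j]])
    if (nj) Bj[lay$bIdx[[j]]] <- theta[off + seq_len(nj)]
    off <- off + nj
    B[[j]] <- Bj
  }
  C <- matrix(0, r, ncol(spec@cMask))
  if (lay$nC) C[lay$cIdx] <- theta[off + seq_len(lay$nC)]
  off <- off + lay$nC
  h <- matrix(.hPriorMeans, r, 6, byrow = TRUE,
              dimnames = list(NULL, .hColumns))
  lat <- matrix(theta[off + seq_len(lay$nH)], nrow = 3)
  for (i in seq_len(r)) h[i, .hFree] <- h[i, .hFree] * exp(lat[, i])
  dcmParams(A, B, C, h)
}

#' Parameter-set index map for a DCM
#'
#' Partition of the packed parameter vector into intrinsic, modulatory,
#' input and hemodynamic sets, for use as the \code{setMap} of
#' [laplaceFreeEnergy()].
#'
#' @param spec a [DCMSpec-class].
#' @return Named list of integer index vectors.
#' @export
dcmParamSets <- function(spec) {
  Filter(length, .packLayout(spec)$sets)
}

#' Sample DCM parameters from their priors
#'
#' @param spec a [DCMSpec-class].
#' @param seed optional integer seed.
#' @return A [DCMParams-class]; entries fixed at zero by the masks are
#'   exactly zero in every draw.
#' @export
samplePrior <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- dcmPriorBelief(spec)
  theta <- rnorm(length(pr@mean), pr@mean, sqrt(diag(pr@cov)))
  dcmUnpack(theta, spec)
}

#' Prior distribution over self-connection half-lives
#'
#' Samples \eqn{A_{ii} \sim N(-1, 0.177^2)}, rejects the (practically
#' impossible, probability ~1e-8) non-negative draws, and transforms to the
#' half-life \eqn{(1/A_{ii})\log 0.5} of the associated exponential decay.
#' The prior is designed so this distribution has mean about 720 ms with
#' about 90% of its mass between 500 and 1000 ms.
#'
#' @param nSamples number of draws (>= 1e4).
#' @param seed optional integer seed.
#' @param sigmaSelf prior SD of the self-connections.
#' @return List with \code{meanHalflife} (ms), \code{fractionIn500To1000},
#'   \code{halflives} (ms, invisible via the list) and \code{nRejected}.
#' @examples
#' halflifePriorStats(1e4, seed = 1)$meanHalflife
#' @export
halflifePriorStats <- function(nSamples = 1e6, seed = NULL,
                               sigmaSelf = 0.177) {
  if (nSamples < 1e4) stop("nSamples must be >= 1e4", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- rnorm(nSamples, -1, sigmaSelf)
  keep <- a < 0
  hl <- (1 / a[keep]) * log(0.5) * 1000  # ms, positive since a < 0
  list(meanHalflife = mean(hl),
       fractionIn500To1000 = mean(hl >= 500 & hl <= 1000),
       nRejected = sum(!keep))
}

.bCube <- function(B, r, nin) {
  arr <- array(0, c(r, r, max(nin, 1L)))
  for (j in seq_along(B)) arr[, , j] <- B[[j]]
  arr
}

#' Integrate the bilinear neurodynamics
#'
#' Fixed-step 4th-order Runge-Kutta integration of
#' \deqn{\dot z = (A + \textstyle\sum_j u_t(j) B^j) z + C u_t}
#' on the fine time grid of the inputs.
#'
#' @param params a [DCMParams-class].
#' @param inputs an [InputSet-class] (fine grid).
#' @param z0 initial neuronal state (default rest, all zero).
#' @return Matrix of neuronal states, one row per fine-grid step, one
#'   column per region.
#' @export
integrateNeurodynamics <- function(params, inputs, z0 = NULL) {
  stopifnot(is(params, "DCMParams"), is(inputs, "InputSet"))
  r <- nrow(params@A)
  if (is.null(z0)) z0 <- numeric(r)
  if (length(z0) != r || !all(is.finite(z0)))
    stop("z0 must be a finite vector with one entry per region", call. = FALSE)
  .neuroRK4(params@A, .bCube(params@B, r, ncol(inputs@u)), params@C,
            inputs@u, inputs@dt, z0)
}

#' Hemodynamic (Balloon) observation model
#'
#' Integrates, per region, the extended Balloon model driven by neuronal
#' activity — vasodilatory signal \eqn{s}, inflow \eqn{f}, venous volume
#' \eqn{v} (Grubb outflow \eqn{v^{1/\alpha}}) and deoxyhemoglobin \eqn{q} —
#' and maps the states to percent BOLD signal change with the revised
#' nonlinear signal equation (coefficients built from \eqn{E_0} and the
#' intra/extravascular ratio \eqn{\epsilon}). The fine-grid response is
#' downsampled to the scan grid (first scan at t = 0).
#'
#' @param states fine-grid neuronal state matrix from
#'   [integrateNeurodynamics()].
#' @param h regions x 6 hemodynamic parameter matrix (natural scale).
#' @param dt fine-grid step (s).
#' @param TR scan repetition time (s); \code{dt} must divide it.
#' @param regionLabels optional labels for the output.
#' @return A [RegionTimeseries-class] of BOLD signal.
#' @export
balloonBold <- function(states, h, dt, TR, regionLabels = NULL) {
  states <- as.matrix(states)
  steps <- TR / dt
  if (abs(steps - round(steps)) > 1e-8)
    stop("dt must divide TR", call. = FALSE)
  steps <- as.integer(round(steps))
  if (nrow(states) %% steps != 0)
    stop("number of fine-grid steps must be a multiple of TR/dt",
         call. = FALSE)
  y <- .balloonRK4(states, as.matrix(h), dt, steps)
  if (is.null(regionLabels)) regionLabels <- paste0("R", seq_len(ncol(y)))
  new("RegionTimeseries", values = y, TR = TR, regionLabels = regionLabels)
}

#' Forward prediction of a DCM
#'
#' Integrates the neurodynamic and hemodynamic equations and returns the
#' predicted BOLD time series; with \code{concat = TRUE} the per-region
#' series are concatenated (fixed region order) into the single prediction
#' vector \eqn{g(\theta)} used by the fitting machinery.
#'
#' @param params a [DCMParams-class].
#' @param spec the [DCMSpec-class] (scan geometry and labels).
#' @param inputs an [InputSet-class] whose fine grid spans
#'   \code{nScans * TR} seconds.
#' @param concat return the concatenated prediction vector instead of a
#'   [RegionTimeseries-class].
#' @return A [RegionTimeseries-class], or a numeric vector of length
#'   \code{nScans * nRegions} when \code{concat = TRUE}.
#' @export
dcmPredict <- function(params, spec, inputs, concat = FALSE) {
  stopifnot(is(spec, "DCMSpec"))
  steps <- round(spec@TR / inputs@dt)
  if (nrow(inputs@u) != spec@nScans * steps)
    stop("inputs must cover nScans * TR seconds on the fine grid",
         call. = FALSE)
  z <- integrateNeurodynamics(params, inputs)
  ts <- balloonBold(z, params@h, inputs@dt, spec@TR,
                    regionLabels = spec@regionLabels)
  if (concat) as.vector(ts@values) else ts
}

#' Full and nested intelligible-speech DCMs
#'
#' The three-region network (P: posterior temporal, F: inferior frontal,
#' A: anterior temporal) with full intrinsic connectivity, auditory input
#' entering P only, and intelligibility modulating the P-to-F connection.
#' The full model additionally lets intelligibility modulate P-to-A
#' (\eqn{b_{AP}}); the nested model fixes \eqn{b_{AP} = 0}, so the two
#' differ in exactly one free parameter.
#'
#' @param nScans scans per region (default 488).
#' @param TR repetition time in seconds (default 2).
#' @return List with [DCMSpec-class] elements \code{full} and \code{nested}.
#' @examples
#' ms <- buildSpeechModels()
#' sum(ms$full@cMask)  # single driving input connection
#' @export
buildSpeechModels <- function(nScans = 488, TR = 2) {
  labels <- c("P", "F", "A")
  aMask <- matrix(1, 3, 3)
  cMask <- cbind(c(1, 0, 0), c(0, 0, 0))   # u_aud drives P; u_int drives none
  bAud <- matrix(0, 3, 3)
  bIntNested <- matrix(0, 3, 3); bIntNested[2, 1] <- 1   # b_FP
  bIntFull <- bIntNested;        bIntFull[3, 1] <- 1     # + b_AP
  mk <- function(bInt) dcmSpec(aMask, list(bAud, bInt), cMask,
                               TR = TR, nScans = nScans,
                               regionLabels = labels,
                               inputLabels = c("u_aud", "u_int"))
  list(full = mk(bIntFull), nested = mk(bIntNested))
}

#' Auditory spike-train inputs for the speech models
#'
#' Builds the fine-grid input set: \code{u_aud} is a train of 1-second
#' auditory events with a configurable inter-onset interval (default one
#' event every 8 s), and \code{u_int} marks every other event as
#' intelligible (it is \code{u_aud} gated by an alternating indicator).
#'
#' @param spec a [DCMSpec-class] (defines duration and fine grid).
#' @param isi inter-onset interval in seconds.
#' @param eventDuration event duration in seconds.
#' @param stepsPerScan fine-grid steps per TR (default 16).
#' @return An [InputSet-class] with inputs \code{u_aud}, \code{u_int}.
#' @export
makeSpeechInputs <- function(spec, isi = 8, eventDuration = 1,
                             stepsPerScan = 16L) {
  dt <- spec@TR / stepsPerScan
  nFine <- spec@nScans * stepsPerScan
  tgrid <- (seq_len(nFine) - 1) * dt
  onsets <- seq(0, max(tgrid), by = isi)
  uAud <- numeric(nFine)
  uInt <- numeric(nFine)
  for (i in seq_along(onsets)) {
    on <- tgrid >= onsets[i] & tgrid < onsets[i] + eventDuration
    uAud[on] <- 1
    if (i %% 2 == 1) uInt[on] <- 1
  }
  new("InputSet", u = cbind(uAud, uInt), dt = dt,
      labels = c("u_aud", "u_int"))
}
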