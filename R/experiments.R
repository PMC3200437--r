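## Study orchestration: full-versus-nested model comparison sweeps over SNR
## and sample size for GLMs and DCMs, and the accuracy/complexity diagnosis
## of a pair of DCM fits.

## counter-based replication seeds: each (grid point, replication) pair is
## independently reproducible from the master seed
.repSeed <- function(master, grid, rep) {
  as.integer((as.numeric(master) + 100003 * grid + 97 * rep) %% 2147483629 + 1)
}

.aggRows <- function(values, axisValue, aggregator, reps, excluded = 0L) {
  ## values: replication x criterion matrix of oriented log Bayes factors
  agg <- if (aggregator == "mean") colMeans(values) else
    apply(values, 2, median)
  data.frame(
    axisValue = axisValue,
    criterion = colnames(values),
    logBF = unname(agg),
    sd = unname(apply(values, 2, sd)),
    lo90 = unname(apply(values, 2, quantile, probs = 0.05)),
    hi90 = unname(apply(values, 2, quantile, probs = 0.95)),
    reps = nrow(values),
    excluded = excluded,
    row.names = NULL)
}

.critVec <- function(cs, withAicc) {
  v <- c(FL = cs@fL, AIC = cs@aic, BIC = cs@bic)
  if (withAicc) v <- c(v, AICc = cs@aicc)
  v
}

#' GLM model-comparison sweep over SNR
#'
#' For each SNR: draw replications from the true (full or nested) GLM at
#' that SNR, fit both models analytically, score them with the free energy,
#' AIC and BIC, and aggregate the oriented log Bayes factor (true model
#' versus the alternative) by the mean. The design matrix is fixed once per
#' sweep; the noise SD is calibrated from prior-predictive draws of the
#' generating model.
#'
#' @param snrGrid positive SNR values.
#' @param reps replications per grid point.
#' @param trueModel generating model, \code{"full"} or \code{"nested"}.
#' @param seed master seed.
#' @param nScans,conditions,basisPerCondition,TR design geometry (defaults:
#'   the 351-scan, 4-condition, 3-basis face design; the nested model drops
#'   the first condition's columns).
#' @param sigmaP prior SD of the coefficients (default 6.05).
#' @param withAicc include AICc among the criteria.
#' @param calibDraws prior draws used for SNR calibration.
#' @return A [SweepResult-class].
#' @export
glmSnrSweep <- function(snrGrid, reps = 1000,
                        trueModel = c("full", "nested"), seed = 1,
                        nScans = 351, conditions = 4, basisPerCondition = 3,
                        TR = 2, sigmaP = 6.05, withAicc = FALSE,
                        calibDraws = 1000) {
  trueModel <- match.arg(trueModel)
  stopifnot(all(snrGrid > 0), reps >= 1)
  Xf <- makeGlmDesign(nScans, conditions, basisPerCondition, TR, seed = seed)
  Xn <- Xf[, -seq_len(basisPerCondition), drop = FALSE]
  Xtrue <- if (trueModel == "full") Xf else Xn
  sigY <- calibrateSnr(glmPriorSignals(Xtrue, sigmaP, calibDraws,
                                       seed = .repSeed(seed, 0, 0)),
                       targetSnr = 1)@signalSd
  rows <- vector("list", length(snrGrid))
  for (gi in seq_along(snrGrid)) {
    snrSpec <- new("SNRSpec", targetSnr = snrGrid[gi], signalSd = sigY,
                   noiseSd = sigY / snrGrid[gi])
    spF <- glmSpec(Xf, sigmaP, snrSpec@noiseSd)
    spN <- glmSpec(Xn, sigmaP, snrSpec@noiseSd)
    vals <- NULL
    for (r in seq_len(reps)) {
      ds <- generateGlmDataset(Xtrue, sigmaP, snrSpec,
                               seed = .repSeed(seed, gi, r))
      cf <- .critVec(glmCriteria(spF, ds$y, withAicc)$criteria, withAicc)
      cn <- .critVec(glmCriteria(spN, ds$y, withAicc)$criteria, withAicc)
      lb <- if (trueModel == "full") cf - cn else cn - cf
      vals <- rbind(vals, lb)
    }
    rows[[gi]] <- .aggRows(vals, snrGrid[gi], "mean", reps)
  }
  new("SweepResult", table = do.call(rbind, rows), axis = "SNR",
      aggregator = "mean", reps = as.integer(reps),
      seed = as.integer(seed), trueModel = trueModel)
}

#' GLM model-comparison sweep over sample size
#'
#' As [glmSnrSweep()] but varying the number of scans at fixed SNR
#' (default 0.5), regenerating the event schedule for each N, and including
#' AICc. Every N must exceed p + 1 for AICc to be defined.
#'
#' @param nGrid scan counts (default 20 values between 32 and 512).
#' @param snr fixed SNR.
#' @inheritParams glmSnrSweep
#' @return A [SweepResult-class].
#' @export
glmNSweep <- function(nGrid = round(seq(32, 512, length.out = 20)),
                      snr = 0.5, reps = 1000,
                      trueModel = c("full", "nested"), seed = 1,
                      conditions = 4, basisPerCondition = 3, TR = 2,
                      sigmaP = 6.05, calibDraws = 1000) {
  trueModel <- match.arg(trueModel)
  p <- conditions * basisPerCondition
  if (any(nGrid <= p + 1))
    stop("every N must exceed p + 1 = ", p + 1, " for AICc", call. = FALSE)
  rows <- vector("list", length(nGrid))
  for (gi in seq_along(nGrid)) {
    n <- nGrid[gi]
    Xf <- makeGlmDesign(n, conditions, basisPerCondition, TR,
                        seed = .repSeed(seed, gi, 0))
    Xn <- Xf[, -seq_len(basisPerCondition), drop = FALSE]
    Xtrue <- if (trueModel == "full") Xf else Xn
    snrSpec <- calibrateSnr(glmPriorSignals(Xtrue, sigmaP, calibDraws,
                                            seed = .repSeed(seed, gi, 1e6)),
                            targetSnr = snr)
    spF <- glmSpec(Xf, sigmaP, snrSpec@noiseSd)
    spN <- glmSpec(Xn, sigmaP, snrSpec@noiseSd)
    vals <- NULL
    for (r in seq_len(reps)) {
      ds <- generateGlmDataset(Xtrue, sigmaP, snrSpec,
                               seed = .repSeed(seed, gi, r))
      cf <- .critVec(glmCriteria(spF, ds$y, TRUE)$criteria, TRUE)
      cn <- .critVec(glmCriteria(spN, ds$y, TRUE)$criteria, TRUE)
      vals <- rbind(vals, if (trueModel == "full") cf - cn else cn - cf)
    }
    rows[[gi]] <- .aggRows(vals, n, "mean", reps)
  }
  new("SweepResult", table = do.call(rbind, rows), axis = "N",
      aggregator = "mean", reps = as.integer(reps),
      seed = as.integer(seed), trueModel = trueModel)
}

#' Fit a DCM to a data vector by variational Laplace
#'
#' Wires a [DCMSpec-class] into [vlFit()]: packs the free parameters,
#' builds the prior from [dcmPriorBelief()], uses per-region i.i.d. noise
#' with the standard hyper-prior, and attaches the per-region accuracy and
#' per-parameter-set complexity decompositions to the result.
#'
#' @param spec a [DCMSpec-class].
#' @param y concatenated data vector (region-major, length
#'   \code{nScans * nRegions}).
#' @param inputs an [InputSet-class].
#' @param options options merged into [vlOptions()].
#' @param withAicc also compute AICc.
#' @return A [FitResult-class].
#' @export
dcmFit <- function(spec, y, inputs, options = list(), withAicc = FALSE) {
  stopifnot(is(spec, "DCMSpec"))
  prior <- dcmPriorBelief(spec)
  noise <- regionNoiseModel(spec@nScans, spec@nRegions,
                            hyperMean = spec@hyperMean,
                            hyperVar = spec@hyperVar)
  g <- function(theta) dcmPredict(dcmUnpack(theta, spec), spec, inputs,
                                  concat = TRUE)
  rmap <- lapply(seq_len(spec@nRegions), function(r)
    seq.int((r - 1L) * spec@nScans + 1L, r * spec@nScans))
  names(rmap) <- spec@regionLabels
  vlFit(g, prior, noise, y, options = options, regionMap = rmap,
        setMap = dcmParamSets(spec), withAicc = withAicc)
}

#' DCM model-comparison sweep over SNR
#'
#' For each SNR: generate replications from the true speech DCM, fit the
#' full and nested models by variational Laplace, score them, and aggregate
#' the oriented log Bayes factor by the median (DCM results are heavier
#' tailed than the GLM case). Replications in which either fit failed to
#' converge are excluded from the median, with the exclusion count
#' reported.
#'
#' @param snrGrid positive SNR values.
#' @param reps replications per grid point (50 at study scale; reducible).
#' @param trueModel generating model.
#' @param seed master seed.
#' @param nScans,TR scan geometry for [buildSpeechModels()].
#' @param options [vlOptions()] overrides passed to the fits.
#' @return A [SweepResult-class].
#' @export
dcmSnrSweep <- function(snrGrid, reps = 50,
                        trueModel = c("full", "nested"), seed = 1,
                        nScans = 488, TR = 2, options = list()) {
  trueModel <- match.arg(trueModel)
  stopifnot(all(snrGrid > 0), reps >= 1)
  models <- buildSpeechModels(nScans = nScans, TR = TR)
  genSpec <- models[[trueModel]]
  inputs <- makeSpeechInputs(genSpec)
  rows <- vector("list", length(snrGrid))
  for (gi in seq_along(snrGrid)) {
    vals <- NULL
    keep <- logical(0)
    for (r in seq_len(reps)) {
      ds <- generateDcmDataset(genSpec, snrGrid[gi], inputs = inputs,
                               seed = .repSeed(seed, gi, r))
      ff <- dcmFit(models$full, ds$y, inputs, options = options)
      fn <- dcmFit(models$nested, ds$y, inputs, options = options)
      cf <- .critVec(ff@criteria, FALSE)
      cn <- .critVec(fn@criteria, FALSE)
      vals <- rbind(vals, if (trueModel == "full") cf - cn else cn - cf)
      keep <- c(keep, ff@converged && fn@converged)
    }
    used <- vals[keep, , drop = FALSE]
    if (!nrow(used)) used <- vals * NA_real_
    rows[[gi]] <- .aggRows(used, snrGrid[gi], "median", reps,
                           excluded = sum(!keep))
  }
  new("SweepResult", table = do.call(rbind, rows), axis = "SNR",
      aggregator = "median", reps = as.integer(reps),
      seed = as.integer(seed), trueModel = trueModel)
}

#' Diagnose a full-versus-nested comparison
#'
#' Decomposes the free-energy difference between two fits of the same data
#' into per-region accuracy differences and per-parameter-set complexity
#' differences, identifying whether accuracy or complexity drives
#' \eqn{\Delta F_L}. The per-set complexity decomposition ignores cross-set
#' posterior correlation and is approximate.
#'
#' @param fitFull,fitNested [FitResult-class] objects fitted to the same
#'   data vector (verified through the stored data signatures).
#' @return List with \code{deltaFL}, \code{deltaAccuracy},
#'   \code{deltaComplexity} (full minus nested; complexity includes the
#'   hyperparameter term), \code{dominantTerm}, and data frames
#'   \code{regionAccuracy} and \code{setComplexity}.
#' @export
decomposeComparison <- function(fitFull, fitNested) {
  stopifnot(is(fitFull, "FitResult"), is(fitNested, "FitResult"))
  if (!isTRUE(all.equal(fitFull@dataSignature, fitNested@dataSignature,
                        tolerance = 1e-10)))
    stop("fits refer to different data vectors", call. = FALSE)
  bf <- fitFull@breakdown; bn <- fitNested@breakdown
  dAcc <- bf@accuracy - bn@accuracy
  dCx <- (bf@complexityParams + bf@complexityHypers) -
    (bn@complexityParams + bn@complexityHypers)
  regions <- union(names(bf@accuracyByRegion), names(bn@accuracyByRegion))
  regionAccuracy <- data.frame(
    region = regions,
    full = unname(bf@accuracyByRegion[regions]),
    nested = unname(bn@accuracyByRegion[regions]),
    row.names = NULL)
  regionAccuracy$delta <- regionAccuracy$full - regionAccuracy$nested
  sets <- union(names(bf@complexityBySet), names(bn@complexityBySet))
  setComplexity <- data.frame(
    set = sets,
    full = unname(bf@complexityBySet[sets]),
    nested = unname(bn@complexityBySet[sets]),
    row.names = NULL)
  setComplexity$delta <- setComplexity$full - setComplexity$nested
  list(deltaFL = bf@fL - bn@fL,
       deltaAccuracy = dAcc,
       deltaComplexity = dCx,
       dominantTerm = if (abs(dCx) >= abs(dAcc)) "complexity" else "accuracy",
       regionAccuracy = regionAccuracy,
       setComplexity = setComplexity)
}
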