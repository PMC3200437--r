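## Accessor generics and show methods. Slots are never reached into from
## user code; these are the supported surface.

#' @name accessors
#' @title Accessors for dcmEvidence objects
#' @description Extract the standard components of beliefs, fits and sweeps
#'   without touching slots directly.
#' @param object an object of the documented class.
NULL

#' @describeIn accessors mean vector of a belief.
#' @export
setGeneric("beliefMean", function(object) standardGeneric("beliefMean"))

#' @describeIn accessors covariance matrix of a belief.
#' @export
setGeneric("beliefCov", function(object) standardGeneric("beliefCov"))

#' @describeIn accessors Laplace free energy of a fit, breakdown or
#'   criterion set.
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))

#' @describeIn accessors posterior mean over parameters.
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))

#' @describeIn accessors posterior covariance over parameters.
#' @export
setGeneric("posteriorCov", function(object) standardGeneric("posteriorCov"))

#' @describeIn accessors the [CriterionSet-class] of a fit.
#' @export
setGeneric("modelCriteria", function(object) standardGeneric("modelCriteria"))

#' @describeIn accessors the [EvidenceBreakdown-class] of a fit.
#' @export
setGeneric("evidenceBreakdown",
           function(object) standardGeneric("evidenceBreakdown"))

#' @describeIn accessors convergence flag of a fit.
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @describeIn accessors tidy results table of a sweep.
#' @export
setGeneric("sweepTable", function(object) standardGeneric("sweepTable"))

#' @describeIn accessors BOLD value matrix of a time series.
#' @export
setGeneric("boldValues", function(object) standardGeneric("boldValues"))

setMethod("beliefMean", "GaussianBelief", function(object) object@mean)
setMethod("beliefCov", "GaussianBelief", function(object) object@cov)
setMethod("freeEnergy", "EvidenceBreakdown", function(object) object@fL)
setMethod("freeEnergy", "CriterionSet", function(object) object@fL)
setMethod("freeEnergy", "FitResult", function(object) object@breakdown@fL)
setMethod("posteriorMean", "FitResult", function(object) object@theta@mean)
setMethod("posteriorCov", "FitResult", function(object) object@theta@cov)
setMethod("modelCriteria", "FitResult", function(object) object@criteria)
setMethod("evidenceBreakdown", "FitResult", function(object) object@breakdown)
setMethod("isConverged", "FitResult", function(object) object@converged)
setMethod("sweepTable", "SweepResult", function(object) object@table)
setMethod("boldValues", "RegionTimeseries", function(object) object@values)

setMethod("show", "GaussianBelief", function(object) {
  d <- length(object@mean)
  cat(sprintf("GaussianBelief over %d parameter%s\n", d,
              if (d == 1) "" else "s"))
  cat("  mean:", paste(signif(utils::head(object@mean, 6), 4),
                       collapse = " "),
      if (d > 6) "...\n" else "\n")
})

setMethod("show", "EvidenceBreakdown", function(object) {
  cat("EvidenceBreakdown\n")
  cat(sprintf("  F_L        : %.4f\n", object@fL))
  cat(sprintf("  accuracy   : %.4f\n", object@accuracy))
  cat(sprintf("  complexity : %.4f (params) + %.4f (hypers)\n",
              object@complexityParams, object@complexityHypers))
  if (length(object@accuracyByRegion))
    cat("  accuracy by region:",
        paste(sprintf("%s=%.3f", names(object@accuracyByRegion),
                      object@accuracyByRegion), collapse = ", "), "\n")
  if (length(object@complexityBySet))
    cat("  complexity by set (approx):",
        paste(sprintf("%s=%.3f", names(object@complexityBySet),
                      object@complexityBySet), collapse = ", "), "\n")
})

setMethod("show", "CriterionSet", function(object) {
  cat(sprintf("CriterionSet (p = %d, N = %d)\n", object@p, object@n))
  cat(sprintf("  F_L = %.4f  AIC = %.4f  BIC = %.4f  AICc = %s\n",
              object@fL, object@aic, object@bic,
              if (is.na(object@aicc)) "NA" else sprintf("%.4f",
                                                        object@aicc)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d iteration%s, %s\n", object@iterations,
              if (object@iterations == 1) "" else "s",
              if (object@converged) "converged" else "NOT converged"))
  show(object@criteria)
})

setMethod("show", "DCMSpec", function(object) {
  cat(sprintf("DCMSpec: %d regions (%s), %d input%s, %d scans at TR = %gs\n",
              object@nRegions, paste(object@regionLabels, collapse = ", "),
              ncol(object@cMask), if (ncol(object@cMask) == 1) "" else "s",
              object@nScans, object@TR))
  cat(sprintf("  free connections: A = %d, B = %d, C = %d\n",
              sum(object@aMask), sum(vapply(object@bMasks, sum, 0)),
              sum(object@cMask)))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %s sweep, true model = %s, %s over %d reps\n",
              object@axis, object@trueModel, object@aggregator,
              object@reps))
  print(utils::head(object@table, 12))
  if (nrow(object@table) > 12)
    cat("  ...", nrow(object@table) - 12, "more rows\n")
})

setMethod("show", "RegionTimeseries", function(object) {
  cat(sprintf("RegionTimeseries: %d scans x %d regions (%s), TR = %gs\n",
              nrow(object@values), ncol(object@values),
              paste(object@regionLabels, collapse = ", "), object@TR))
})

setMethod("show", "SNRSpec", function(object) {
  cat(sprintf("SNRSpec: target %.4g = signal SD %.4g / noise SD %.4g\n",
              object@targetSnr, object@signalSd, object@noiseSd))
})
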