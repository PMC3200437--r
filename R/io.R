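## Plain-text serialisation: flat JSON records for evidence summaries, CSV
## plus JSON sidecars for time series and designs, JSON round-trips for DCM
## structures and sweep tables.

#' Flat evidence record
#'
#' Collapses an [EvidenceBreakdown-class] and [CriterionSet-class] into one
#' flat named list suitable for a JSON row: keys \code{f_l},
#' \code{accuracy}, \code{complexity_params}, \code{complexity_hypers},
#' \code{aic}, \code{bic}, \code{aicc}, \code{p}, \code{n}, plus
#' per-region accuracies (\code{accuracy_region_*}) and per-set
#' complexities (\code{complexity_set_*}, flagged approximate).
#'
#' @param breakdown an [EvidenceBreakdown-class].
#' @param criteria a [CriterionSet-class].
#' @return Named list of scalars.
#' @export
asEvidenceRecord <- function(breakdown, criteria) {
  rec <- list(f_l = breakdown@fL,
              accuracy = breakdown@accuracy,
              complexity_params = breakdown@complexityParams,
              complexity_hypers = breakdown@complexityHypers,
              aic = criteria@aic, bic = criteria@bic, aicc = criteria@aicc,
              p = criteria@p, n = criteria@n)
  for (nm in names(breakdown@accuracyByRegion))
    rec[[paste0("accuracy_region_", nm)]] <- breakdown@accuracyByRegion[[nm]]
  for (nm in names(breakdown@complexityBySet))
    rec[[paste0("complexity_set_", nm)]] <- breakdown@complexityBySet[[nm]]
  if (length(breakdown@complexityBySet))
    rec$complexity_by_set_approximate <- TRUE
  rec
}

#' Serialise a fit to JSON
#'
#' Writes the posterior beliefs (mean and covariance), the flat evidence
#' record and the free-energy trajectory of a [FitResult-class].
#'
#' @param fit a [FitResult-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeFitResult <- function(fit, path) {
  obj <- list(
    theta = list(mean = fit@theta@mean, cov = fit@theta@cov),
    lambda = list(mean = fit@lambda@mean, cov = fit@lambda@cov),
    evidence = asEvidenceRecord(fit@breakdown, fit@criteria),
    iterations = fit@iterations, converged = fit@converged,
    trajectory = fit@trajectory)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Write / read a multi-region time series
#'
#' CSV with one column per region (header = region labels) plus a JSON
#' sidecar (\code{<path>.json}) holding TR and any extra metadata such as
#' the generating seed.
#'
#' @param ts a [RegionTimeseries-class].
#' @param path CSV path.
#' @param meta named list of extra metadata for the sidecar.
#' @return \code{writeRegionTimeseries}: invisibly, the path;
#'   \code{readRegionTimeseries}: a [RegionTimeseries-class].
#' @export
writeRegionTimeseries <- function(ts, path, meta = list()) {
  df <- as.data.frame(ts@values)
  names(df) <- ts@regionLabels
  write.csv(df, path, row.names = FALSE)
  side <- c(list(TR = ts@TR, regionLabels = ts@regionLabels), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeRegionTimeseries
#' @export
readRegionTimeseries <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("RegionTimeseries", values = as.matrix(df), TR = side$TR,
      regionLabels = names(df))
}

#' Write / read a DCM structure as JSON
#'
#' @param spec a [DCMSpec-class].
#' @param path file path.
#' @return \code{writeDcmSpec}: invisibly, the path; \code{readDcmSpec}:
#'   a [DCMSpec-class].
#' @export
writeDcmSpec <- function(spec, path) {
  obj <- list(nRegions = spec@nRegions, aMask = spec@aMask,
              bMasks = spec@bMasks, cMask = spec@cMask,
              sigmaSelf = spec@sigmaSelf, sigmaCross = spec@sigmaCross,
              sigmaS = spec@sigmaS, hyperMean = spec@hyperMean,
              hyperVar = spec@hyperVar, TR = spec@TR, nScans = spec@nScans,
              regionLabels = spec@regionLabels,
              inputLabels = spec@inputLabels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeDcmSpec
#' @export
readDcmSpec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  dcmSpec(o$aMask, if (is.list(o$bMasks)) o$bMasks else
            lapply(seq_len(dim(o$bMasks)[1]), function(i) o$bMasks[i, , ]),
          o$cMask, TR = o$TR, nScans = o$nScans,
          regionLabels = o$regionLabels, inputLabels = o$inputLabels,
          sigmaSelf = o$sigmaSelf, sigmaCross = o$sigmaCross,
          sigmaS = o$sigmaS, hyperMean = o$hyperMean, hyperVar = o$hyperVar)
}

#' Write / read DCM parameter values as JSON
#'
#' @param params a [DCMParams-class].
#' @param path file path.
#' @return \code{writeDcmParams}: invisibly, the path;
#'   \code{readDcmParams}: a [DCMParams-class].
#' @export
writeDcmParams <- function(params, path) {
  jsonlite::write_json(list(A = params@A, B = params@B, C = params@C,
                            h = params@h),
                       path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeDcmParams
#' @export
readDcmParams <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- if (is.list(o$B)) o$B else
    lapply(seq_len(dim(o$B)[1]), function(i) o$B[i, , ])
  h <- as.matrix(o$h); colnames(h) <- .hColumns
  dcmParams(o$A, B, o$C, h)
}

#' Write a sweep to CSV with a JSON run manifest
#'
#' The tidy table (one row per grid point and criterion) goes to
#' \code{path}; the manifest (\code{<path>.json}) records axis, aggregator,
#' replication count, generating model and master seed so the sweep can be
#' reproduced exactly.
#'
#' @param sweep a [SweepResult-class].
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
writeSweepResult <- function(sweep, path) {
  write.csv(sweep@table, path, row.names = FALSE)
  jsonlite::write_json(list(axis = sweep@axis,
                            aggregator = sweep@aggregator,
                            reps = sweep@reps, seed = sweep@seed,
                            trueModel = sweep@trueModel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a design matrix as headered CSV
#'
#' @param design design matrix.
#' @param path CSV path.
#' @return \code{writeDesignCsv}: invisibly, the path;
#'   \code{readDesignCsv}: a numeric matrix.
#' @export
writeDesignCsv <- function(design, path) {
  write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignCsv
#' @export
readDesignCsv <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}
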