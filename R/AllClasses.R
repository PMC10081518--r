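#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rnorm runif rbinom sd quantile coef lm setNames aggregate
#'   complete.cases cor predict
#' @importFrom utils head read.csv write.csv
NULL

#' Configuration of the synthetic smoke-episode domain
#'
#' A `DomainConfig` holds every parameter of the synthetic study domain:
#' grid geometry, episode length, monitor/sensor network sizes, plume and
#' background intensity, sensor bias structure, and satellite retrieval
#' behaviour. All simulation output is a pure function of a `DomainConfig`
#' (including its `seed`).
#'
#' @slot nx,ny Grid dimensions (cells).
#' @slot cellDxKm,cellDyKm Cell size along x (east) and y (north), km.
#' @slot nHours Episode length in hours.
#' @slot nAqs Number of regulatory ("AQS-like") monitors.
#' @slot nPurpleair Number of low-cost ("PurpleAir-like") sensors.
#' @slot plumeAmplitude Peak plume PM2.5 contribution (ug/m3).
#' @slot plumeSigmaKm Spatial scale (Gaussian sigma) of the plume, km.
#' @slot backgroundMean,backgroundSd Mean and SD of the ambient (non-plume)
#'   PM2.5 field (ug/m3); realised as a log-normal field.
#' @slot aqsReportProb Per-hour reporting probability of an AQS monitor.
#' @slot paReportProb Per-hour reporting probability of a low-cost sensor.
#' @slot aqsNoiseSd Measurement noise SD of AQS monitors (ug/m3).
#' @slot paBiasAdd Additive low-cost sensor bias (ug/m3).
#' @slot paBiasRhCoef Low-cost sensor bias per percent relative humidity,
#'   applied to the deviation of RH from `rhMean` so that `paBiasAdd` remains
#'   the mean raw bias.
#' @slot paBiasMult Multiplicative low-cost sensor bias (fraction of truth).
#' @slot paNoiseSd Low-cost sensor noise SD (ug/m3).
#' @slot aodMissingFracBase Baseline AOD retrieval-failure probability; the
#'   failure probability additionally increases with the true PM2.5 column
#'   (retrievals fail preferentially inside thick smoke).
#' @slot aodSlope Proportionality constant AOD per (ug/m3) of PM2.5.
#' @slot aodNoiseSd AOD retrieval noise SD (unitless).
#' @slot rhMean Domain-mean relative humidity (percent).
#' @slot smokeMaskThreshold Plume PM2.5 (ug/m3) above which the satellite
#'   smoke mask flags a cell.
#' @slot nPaClusters Number of spatial clusters the low-cost sensors form.
#' @slot paClusterSdKm Within-cluster spread (Gaussian sigma), km.
#' @slot nCollocated Number of low-cost sensors placed within collocation
#'   range (~300 m) of an AQS monitor, enabling calibration.
#' @slot originLon,originLat Lon/lat (degrees) of the grid's south-west
#'   corner.
#' @slot seed Integer seed; identical configs give bit-identical output.
#'
#' @seealso [domainConfig()] for the user-facing constructor with defaults.
#' @export
setClass("DomainConfig", representation(
  nx = "integer", ny = "integer",
  cellDxKm = "numeric", cellDyKm = "numeric",
  nHours = "integer",
  nAqs = "integer", nPurpleair = "integer",
  plumeAmplitude = "numeric", plumeSigmaKm = "numeric",
  backgroundMean = "numeric", backgroundSd = "numeric",
  aqsReportProb = "numeric", paReportProb = "numeric",
  aqsNoiseSd = "numeric",
  paBiasAdd = "numeric", paBiasRhCoef = "numeric", paBiasMult = "numeric",
  paNoiseSd = "numeric",
  aodMissingFracBase = "numeric", aodSlope = "numeric", aodNoiseSd = "numeric",
  rhMean = "numeric", smokeMaskThreshold = "numeric",
  nPaClusters = "integer", paClusterSdKm = "numeric", nCollocated = "integer",
  originLon = "numeric", originLat = "numeric",
  seed = "integer"
))

setValidity("DomainConfig", function(object) {
  msgs <- character()
  pos <- c(nx = object@nx, ny = object@ny, nHours = object@nHours,
           nAqs = object@nAqs, nPurpleair = object@nPurpleair,
           plumeSigmaKm = object@plumeSigmaKm,
           cellDxKm = object@cellDxKm, cellDyKm = object@cellDyKm)
  bad <- names(pos)[pos <= 0]
  if (length(bad))
    msgs <- c(msgs, paste0("fields must be positive: ",
                           paste(bad, collapse = ", ")))
  prob <- c(aqsReportProb = object@aqsReportProb,
            paReportProb = object@paReportProb,
            aodMissingFracBase = object@aodMissingFracBase)
  badp <- names(prob)[prob < 0 | prob > 1]
  if (length(badp))
    msgs <- c(msgs, paste0("probabilities must lie in [0,1]: ",
                           paste(badp, collapse = ", ")))
  if (object@plumeAmplitude < 0)
    msgs <- c(msgs, "plumeAmplitude must be >= 0")
  if (object@nAqs + object@nPurpleair > object@nx * object@ny)
    msgs <- c(msgs, "more stations than grid cells")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic smoke-episode domain
#'
#' A `FireDomain` extends [SummarizedExperiment::SummarizedExperiment]:
#' rows are grid cells, columns are hours. Assays are per-field cell-by-hour
#' matrices (`pm25_truth`, `plume`, and after [simulatePredictors()] the
#' satellite and meteorology fields). `rowData` carries cell-center
#' coordinates and static land-use/elevation/road covariates; `colData`
#' carries the per-hour plume track and domain wind; `metadata(x)$config`
#' stores the generating [DomainConfig-class].
#'
#' @export
setClass("FireDomain", contains = "SummarizedExperiment")

#' Geographically weighted calibration model for low-cost sensors
#'
#' Local regression of regulatory PM2.5 on raw sensor PM2.5 and sensor
#' covariates, with one coefficient vector per anchor (each anchor is a
#' collocated sensor site) and Gaussian spatial kernel weights.
#'
#' @slot anchors data.frame with columns `paStationId`, `lon`, `lat`.
#' @slot coefficients numeric matrix, one row per anchor, columns
#'   `(Intercept)`, `paPm25`, `temperature`, `relativeHumidity`, `uptime`,
#'   `operatingTime`.
#' @slot bandwidthKm Gaussian kernel bandwidth (km), > 0.
#' @slot kernel Kernel label (currently `"gaussian"`).
#' @export
setClass("GwrModel", representation(
  anchors = "data.frame",
  coefficients = "matrix",
  bandwidthKm = "numeric",
  kernel = "character"
))

setValidity("GwrModel", function(object) {
  msgs <- character()
  if (nrow(object@anchors) != nrow(object@coefficients))
    msgs <- c(msgs, "one coefficient vector per anchor required")
  if (length(object@bandwidthKm) != 1 || object@bandwidthKm <= 0)
    msgs <- c(msgs, "bandwidthKm must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Cross-validation fold plan
#'
#' Either a temporal plan (`kind = "TEMPORAL_10FOLD"`, one fold id per row
#' of the feature table it was built from) or a spatial plan
#' (`kind = "SPATIAL_LEAVE_TEN_OUT"`, one group id per monitor, named by
#' station id; all of a monitor's observations travel with its group).
#'
#' @slot kind `"TEMPORAL_10FOLD"` or `"SPATIAL_LEAVE_TEN_OUT"`.
#' @slot assignments Integer fold/group ids; named by station id for
#'   spatial plans.
#' @slot nFolds Number of folds/groups.
#' @export
setClass("FoldPlan", representation(
  kind = "character",
  assignments = "integer",
  nFolds = "integer"
))

setValidity("FoldPlan", function(object) {
  msgs <- character()
  if (!object@kind %in% c("TEMPORAL_10FOLD", "SPATIAL_LEAVE_TEN_OUT"))
    msgs <- c(msgs, "unknown fold plan kind")
  if (object@nFolds < 1L)
    msgs <- c(msgs, "nFolds must be >= 1")
  if (length(object@assignments) &&
      !all(object@assignments %in% seq_len(object@nFolds)))
    msgs <- c(msgs, "assignments must index folds 1..nFolds")
  if (object@kind == "SPATIAL_LEAVE_TEN_OUT" &&
      is.null(names(object@assignments)))
    msgs <- c(msgs, "spatial assignments must be named by station id")
  if (length(msgs)) msgs else TRUE
})

#' Hourly PM2.5 prediction surface
#'
#' One predicted PM2.5 value per grid cell for a single hour; `NA` where any
#' predictor is missing. Values are floored at 0 ug/m3.
#'
#' @slot hour Hour index (0-based).
#' @slot values Numeric vector, one value per cell in cell-id order.
#' @slot nx,ny Grid dimensions.
#' @slot lon,lat Cell-center coordinates (degrees), cell-id order.
#' @slot provenance List: model variant, seed, config hash.
#' @export
setClass("PredictionSurface", representation(
  hour = "integer",
  values = "numeric",
  nx = "integer", ny = "integer",
  lon = "numeric", lat = "numeric",
  provenance = "list"
))

setValidity("PredictionSurface", function(object) {
  msgs <- character()
  n <- object@nx * object@ny
  if (length(object@values) != n)
    msgs <- c(msgs, "values must have one entry per grid cell")
  if (any(object@values < 0, na.rm = TRUE))
    msgs <- c(msgs, "predictions must be >= 0 (floored)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DomainConfig", function(object) {
  cat("DomainConfig:", object@nx, "x", object@ny, "cells (",
      object@cellDxKm, "x", object@cellDyKm, "km ),",
      object@nHours, "hours\n")
  cat("  networks:", object@nAqs, "AQS,", object@nPurpleair,
      "PurpleAir (", object@nCollocated, "collocated,",
      object@nPaClusters, "clusters )\n")
  cat("  plume: amplitude", object@plumeAmplitude, "ug/m3, sigma",
      object@plumeSigmaKm, "km; background", object@backgroundMean,
      "+/-", object@backgroundSd, "ug/m3\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "FireDomain", function(object) {
  cat("FireDomain:", nrow(object), "cells x", ncol(object), "hours\n")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})

setMethod("show", "GwrModel", function(object) {
  cat("GwrModel:", nrow(object@anchors), "anchors,",
      object@kernel, "kernel, bandwidth", round(object@bandwidthKm, 2),
      "km\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", object@kind, "-", object@nFolds, "folds over",
      length(object@assignments),
      if (object@kind == "SPATIAL_LEAVE_TEN_OUT") "monitors\n" else "rows\n")
})

setMethod("show", "PredictionSurface", function(object) {
  cat("PredictionSurface: hour", object@hour, "-", object@nx, "x",
      object@ny, "cells;", sum(!is.na(object@values)), "predicted,",
      sum(is.na(object@values)), "missing\n")
})

# ---- accessors ------------------------------------------------------------

#' @describeIn DomainConfig-class Retrieve the config stored in a
#'   [FireDomain-class].
#' @param domain A `FireDomain`.
#' @export
domainConfigOf <- function(domain) {
  stopifnot(is(domain, "FireDomain"))
  S4Vectors::metadata(domain)$config
}

#' Extract the true PM2.5 field of a synthetic domain
#'
#' @param domain A [FireDomain-class].
#' @return cells-by-hours matrix of true PM2.5 (ug/m3).
#' @export
truthField <- function(domain) {
  SummarizedExperiment::assay(domain, "pm25_truth")
}

#' Extract the plume-only PM2.5 component of a synthetic domain
#'
#' @param domain A [FireDomain-class].
#' @return cells-by-hours matrix of the plume contribution (ug/m3).
#' @export
plumeField <- function(domain) {
  SummarizedExperiment::assay(domain, "plume")
}

#' Cell-center geometry of a domain
#'
#' @param domain A [FireDomain-class].
#' @return data.frame: `cellId` (0-based), `gridCol`, `gridRow` (0-based),
#'   `lon`, `lat`, `xKm`, `yKm`.
#' @export
cellCenters <- function(domain) {
  rd <- SummarizedExperiment::rowData(domain)
  data.frame(cellId = rd$cellId, gridCol = rd$gridCol, gridRow = rd$gridRow,
             lon = rd$lon, lat = rd$lat, xKm = rd$xKm, yKm = rd$yKm)
}

#' @describeIn PredictionSurface-class Values as an `ny`-by-`nx` matrix
#'   (row 1 = southernmost row).
#' @param surface A `PredictionSurface`.
#' @export
surfaceMatrix <- function(surface) {
  matrix(surface@values, nrow = surface@ny, ncol = surface@nx, byrow = TRUE)
}
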