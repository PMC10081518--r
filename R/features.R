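#' Predictor columns of the model feature table, in fixed order
#'
#' The order is identical across all rows and models; `convPm25` is the
#' inverse-distance-weighted neighbor layer.
#' @export
predictorNames <- c("aod", "smokeMask", "dustMask", "aerosolMask",
                    "t2m", "pressure", "u10", "v10", "pblh", "rh",
                    "elevation", "developedFrac", "forestFrac", "shrubFrac",
                    "herbFrac", "roadDistKm", "convPm25")

binaryPredictorNames <- c("smokeMask", "dustMask", "aerosolMask")

#' Inverse-distance-weighted neighbor layer
#'
#' For each target cell-hour, the IDW average of the `k` nearest same-hour
#' ground measurements, with great-circle distances between cell centers:
#' `sum(v_i / d_i) / sum(1 / d_i)`. The target cell's own measurement is
#' excluded when `selfExclude = TRUE` (always the case for training rows,
#' guarding against target leakage). Fewer than `k` neighbors: all
#' available are used; none: `NA`. An exact zero distance returns that
#' neighbor's value.
#'
#' @param targets data.frame `cellId`, `hour` of the cell-hours to fill.
#' @param ground Deduplicated ground values ([dedupGround()] schema).
#' @param domain A [FireDomain-class] (for cell-center coordinates).
#' @param k Number of neighbors (default 5).
#' @param selfExclude Drop the target cell's own same-hour measurement.
#' @return Numeric vector aligned with `targets` rows (ug/m3, `NA` when no
#'   neighbor exists).
#' @export
convolutionalLayer <- function(targets, ground, domain, k = 5,
                               selfExclude = TRUE) {
  geom <- cellCenters(domain)
  lonOf <- geom$lon[match(targets$cellId, geom$cellId)]
  latOf <- geom$lat[match(targets$cellId, geom$cellId)]
  gLon <- geom$lon[match(ground$cellId, geom$cellId)]
  gLat <- geom$lat[match(ground$cellId, geom$cellId)]
  out <- rep(NA_real_, nrow(targets))
  for (h in unique(targets$hour)) {
    ti <- which(targets$hour == h)
    gi <- which(ground$hour == h)
    if (!length(gi)) next
    for (t in ti) {
      keep <- gi
      if (selfExclude)
        keep <- keep[ground$cellId[keep] != targets$cellId[t]]
      if (!length(keep)) next
      d <- greatCircleM(lonOf[t], latOf[t], gLon[keep], gLat[keep])
      ord <- order(d, ground$cellId[keep])
      use <- ord[seq_len(min(k, length(ord)))]
      dd <- d[use]; vv <- ground$pm25[keep][use]
      if (any(dd == 0)) {
        out[t] <- vv[which(dd == 0)[1]]
      } else {
        out[t] <- sum(vv / dd) / sum(1 / dd)
      }
    }
  }
  out
}

# pull predictor values for (cellId, hour) pairs from the domain
predictorFrame <- function(domain, cellId, hour) {
  rd <- as.data.frame(SummarizedExperiment::rowData(domain))
  ci <- cellId + 1L; hi <- hour + 1L
  a <- function(nm) SummarizedExperiment::assay(domain, nm)[cbind(ci, hi)]
  data.frame(
    aod = a("aod"), smokeMask = a("smoke_mask"), dustMask = a("dust_mask"),
    aerosolMask = a("aerosol_mask"), t2m = a("t2m"),
    pressure = a("pressure"), u10 = a("u10"), v10 = a("v10"),
    pblh = a("pblh"), rh = a("rh"),
    elevation = rd$elevation[ci], developedFrac = rd$developedFrac[ci],
    forestFrac = rd$forestFrac[ci], shrubFrac = rd$shrubFrac[ci],
    herbFrac = rd$herbFrac[ci], roadDistKm = rd$roadDistKm[ci])
}

#' Assemble the model-ready feature table
#'
#' Training mode builds one row per deduplicated ground cell-hour (target =
#' the measured PM2.5, neighbor layer with self-exclusion). Prediction mode
#' builds one row per cell for the requested hours (no target; the neighbor
#' layer uses all same-hour ground measurements). Rows are flagged
#' `complete` when every predictor is non-missing; only complete rows are
#' eligible for training or prediction.
#'
#' @param domain A [FireDomain-class] with predictors.
#' @param ground Deduplicated ground values ([dedupGround()] schema).
#' @param mode `"training"` or `"prediction"`.
#' @param hours Hours to cover in prediction mode (default: all).
#' @param k Neighbors for the IDW layer.
#' @return data.frame with `cellId`, `hour`, `stationId`, `network`,
#'   `weight`, `pm25` (NA in prediction mode), the [predictorNames]
#'   columns, and `complete`.
#' @export
assembleFeatures <- function(domain, ground, mode = c("training", "prediction"),
                             hours = NULL, k = 5) {
  mode <- match.arg(mode)
  if (mode == "training") {
    base <- data.frame(cellId = ground$cellId, hour = ground$hour,
                       stationId = ground$stationId,
                       network = ground$network, weight = ground$weight,
                       pm25 = ground$pm25)
    conv <- convolutionalLayer(base, ground, domain, k = k,
                               selfExclude = TRUE)
  } else {
    if (is.null(hours)) hours <- SummarizedExperiment::colData(domain)$hour
    nCell <- nrow(domain)
    base <- data.frame(
      cellId = rep(seq_len(nCell) - 1L, times = length(hours)),
      hour = rep(as.integer(hours), each = nCell),
      stationId = NA_character_, network = NA_character_,
      weight = NA_real_, pm25 = NA_real_)
    conv <- convolutionalLayer(base, ground, domain, k = k,
                               selfExclude = FALSE)
  }
  ft <- cbind(base, predictorFrame(domain, base$cellId, base$hour))
  ft$convPm25 <- conv
  ft$complete <- complete.cases(ft[, predictorNames])
  if (mode == "training" && !any(ft$complete))
    stop("no complete training rows (all rows miss at least one predictor)")
  rownames(ft) <- NULL
  ft
}

#' Keep only rows with every predictor present
#'
#' @param features A feature table from [assembleFeatures()].
#' @return The complete rows.
#' @export
completeFeatures <- function(features) {
  features[features$complete, , drop = FALSE]
}
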