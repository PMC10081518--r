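#' Aggregate sub-hourly satellite records to the hour
#'
#' AOD retrievals are averaged over the valid sub-hourly records of each
#' cell-hour; binary detection masks (smoke, dust, aerosol) take the
#' any-rule (1 if any valid sub-hourly record is 1). Cell-hours with zero
#' valid records are `NA`. Aggregation is invariant to record order.
#'
#' @param records data.frame with columns `cellId`, `hour`, `product`
#'   (one of `"aod"`, `"smoke"`, `"dust"`, `"aerosol"`), `value`, `valid`
#'   (logical/0-1 retrieval quality flag).
#' @return data.frame `cellId`, `hour`, `product`, `value` with one row per
#'   cell-hour-product present in the input (`NA` value when no valid
#'   record exists).
#' @export
aggregateSatelliteHourly <- function(records) {
  cols <- c("cellId", "hour", "product", "value", "valid")
  stopifnot(all(cols %in% names(records)))
  if (!nrow(records))
    return(data.frame(cellId = integer(), hour = integer(),
                      product = character(), value = numeric()))
  key <- interaction(records$cellId, records$hour, records$product,
                     drop = TRUE)
  agg <- function(idx) {
    v <- records$value[idx][as.logical(records$valid[idx])]
    if (!length(v)) return(NA_real_)
    if (records$product[idx[1]] == "aod") mean(v) else as.numeric(any(v == 1))
  }
  idxs <- split(seq_len(nrow(records)), key)
  first <- vapply(idxs, `[`, integer(1), 1L)
  data.frame(cellId = records$cellId[first],
             hour = records$hour[first],
             product = records$product[first],
             value = vapply(idxs, agg, numeric(1)),
             row.names = NULL)
}

#' Injectively join meteorology points to grid cells
#'
#' Assigns meteorology points to grid cells by a greedy nearest-neighbor
#' walk over all (point, cell) pairs in increasing great-circle distance
#' (ties broken by point id then cell id), so that no point is joined to
#' two cells and no cell receives two points. Cells left without a point
#' (when there are fewer points than cells) inherit the point of their
#' nearest assigned cell and are flagged `inherited`.
#'
#' @param metPoints data.frame: `pointId`, `lon`, `lat` (plus any field
#'   columns, which are carried along).
#' @param cells data.frame: `cellId`, `lon`, `lat`.
#' @return data.frame, one row per cell: `cellId`, `pointId`,
#'   `distanceM` (to the directly assigned point, `NA` when inherited),
#'   `inherited`.
#' @export
joinMetToGrid <- function(metPoints, cells) {
  if (!nrow(metPoints)) stop("zero meteorology points")
  stopifnot(nrow(cells) > 0)
  metPoints <- metPoints[order(metPoints$pointId), ]
  cells <- cells[order(cells$cellId), ]
  np <- nrow(metPoints); nc <- nrow(cells)
  d <- outer(seq_len(np), seq_len(nc), function(i, j)
    greatCircleM(metPoints$lon[i], metPoints$lat[i],
                 cells$lon[j], cells$lat[j]))
  ord <- order(as.vector(d),
               rep(metPoints$pointId, times = nc),
               rep(cells$cellId, each = np))
  pointUsed <- logical(np); cellUsed <- logical(nc)
  assign <- rep(NA_integer_, nc)
  left <- min(np, nc)
  for (k in ord) {
    if (left == 0L) break
    i <- (k - 1L) %% np + 1L
    j <- (k - 1L) %/% np + 1L
    if (pointUsed[i] || cellUsed[j]) next
    pointUsed[i] <- TRUE; cellUsed[j] <- TRUE
    assign[j] <- i
    left <- left - 1L
  }
  out <- data.frame(cellId = cells$cellId,
                    pointId = metPoints$pointId[assign],
                    distanceM = d[cbind(assign, seq_len(nc))],
                    inherited = FALSE)
  if (any(is.na(assign))) {
    done <- which(!is.na(assign))
    for (j in which(is.na(assign))) {
      dj <- greatCircleM(cells$lon[j], cells$lat[j],
                         cells$lon[done], cells$lat[done])
      src <- done[which.min(dj)]
      out$pointId[j] <- metPoints$pointId[assign[src]]
      out$inherited[j] <- TRUE
    }
  }
  out
}

#' Deduplicate ground observations to one value per cell-hour
#'
#' Regulatory (AQS) measurements supersede low-cost ones: in a cell-hour
#' containing both networks only the AQS values are kept. Multiple values
#' of the surviving network are averaged. AQS cell-hours receive weight 1;
#' low-cost cell-hours receive `weightPa` (default 0.15). Each deduplicated
#' row records a primary station (the lexicographically first contributing
#' station of the kept network) used to tie rows to spatial CV groups.
#'
#' @param obs Observation data.frame with `stationId`, `network`, `cellId`,
#'   `hour`, `pm25` (calibrated for the low-cost network).
#' @param weightPa Observation weight of low-cost cell-hours, in (0, 1].
#' @return data.frame, one row per observed cell-hour: `cellId`, `hour`,
#'   `pm25`, `network`, `weight`, `stationId` (primary), `nStations`.
#' @export
dedupGround <- function(obs, weightPa = 0.15) {
  stopifnot(weightPa > 0, weightPa <= 1)
  if (!nrow(obs))
    return(data.frame(cellId = integer(), hour = integer(), pm25 = numeric(),
                      network = character(), weight = numeric(),
                      stationId = character(), nStations = integer()))
  key <- paste(obs$cellId, obs$hour, sep = "_")
  hasAqs <- tapply(obs$network == "AQS", key, any)
  keepNet <- ifelse(hasAqs[key], "AQS", "PURPLEAIR")
  kept <- obs[obs$network == keepNet, ]
  kkey <- paste(kept$cellId, kept$hour, sep = "_")
  idxs <- split(seq_len(nrow(kept)), kkey)
  first <- vapply(idxs, `[`, integer(1), 1L)
  data.frame(
    cellId = kept$cellId[first],
    hour = kept$hour[first],
    pm25 = vapply(idxs, function(i) mean(kept$pm25[i]), numeric(1)),
    network = kept$network[first],
    weight = ifelse(kept$network[first] == "AQS", 1, weightPa),
    stationId = vapply(idxs, function(i) min(kept$stationId[i]),
                       character(1)),
    nStations = vapply(idxs, function(i) length(unique(kept$stationId[i])),
                       integer(1)),
    row.names = NULL)
}
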