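#' Find collocated low-cost / regulatory station pairs
#'
#' A low-cost sensor is collocated with a regulatory monitor when their
#' great-circle distance is at most `radiusM` (default 500 m). If several
#' monitors qualify, the sensor pairs with the nearest one (ties broken by
#' station-id lexical order, so pairing is reproducible). Pairs are then
#' expanded to hours in which both members reported.
#'
#' @param aqsObs,paObs Observation data.frames (schema of
#'   [sampleNetworks()]); `paObs` rows must carry temperature, relative
#'   humidity, uptime and operating time.
#' @param radiusM Collocation radius, meters.
#' @return data.frame, one row per collocated station pair and hour:
#'   `paStationId`, `aqsStationId`, `distanceM`, `hour`, `paPm25`,
#'   `aqsPm25`, `temperature`, `relativeHumidity`, `uptime`,
#'   `operatingTime`, `paLon`, `paLat`. Empty networks give an empty frame.
#' @export
findCollocations <- function(aqsObs, paObs, radiusM = 500) {
  empty <- data.frame(paStationId = character(), aqsStationId = character(),
                      distanceM = numeric(), hour = integer(),
                      paPm25 = numeric(), aqsPm25 = numeric(),
                      temperature = numeric(), relativeHumidity = numeric(),
                      uptime = numeric(), operatingTime = numeric(),
                      paLon = numeric(), paLat = numeric())
  if (!nrow(aqsObs) || !nrow(paObs)) return(empty)
  aqsSt <- unique(aqsObs[, c("stationId", "lon", "lat")])
  paSt <- unique(paObs[, c("stationId", "lon", "lat")])
  aqsSt <- aqsSt[order(aqsSt$stationId), ]
  paSt <- paSt[order(paSt$stationId), ]

  out <- vector("list", nrow(paSt))
  for (i in seq_len(nrow(paSt))) {
    d <- greatCircleM(paSt$lon[i], paSt$lat[i], aqsSt$lon, aqsSt$lat)
    ok <- which(d <= radiusM)
    if (!length(ok)) next
    # nearest qualifying monitor; lexical tie-break is implied by the
    # station-id sort order of aqsSt
    j <- ok[which.min(d[ok])]
    pa <- paObs[paObs$stationId == paSt$stationId[i], ]
    aq <- aqsObs[aqsObs$stationId == aqsSt$stationId[j], ]
    m <- match(pa$hour, aq$hour)
    keep <- !is.na(m)
    if (!any(keep)) next
    pa <- pa[keep, ]
    out[[i]] <- data.frame(
      paStationId = pa$stationId, aqsStationId = aqsSt$stationId[j],
      distanceM = d[j], hour = pa$hour,
      paPm25 = pa$pm25, aqsPm25 = aq$pm25[m[keep]],
      temperature = pa$temperature, relativeHumidity = pa$relativeHumidity,
      uptime = pa$uptime, operatingTime = pa$operatingTime,
      paLon = pa$lon, paLat = pa$lat)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

gwrCovariates <- c("paPm25", "temperature", "relativeHumidity",
                   "uptime", "operatingTime")

gwrDesign <- function(pairs) {
  X <- cbind(1, as.matrix(pairs[, gwrCovariates]))
  colnames(X) <- c("(Intercept)", gwrCovariates)
  X
}

# weighted least squares with rank check; returns NULL if rank-deficient
wlsOrNull <- function(X, y, w) {
  keep <- w > 1e-12
  if (sum(keep) < ncol(X)) return(NULL)
  Xw <- X[keep, , drop = FALSE] * sqrt(w[keep])
  qr. <- qr(Xw)
  if (qr.$rank < ncol(X)) return(NULL)
  as.numeric(qr.coef(qr., y[keep] * sqrt(w[keep])))
}

#' Fit a geographically weighted calibration of low-cost sensors
#'
#' At every anchor (a unique collocated sensor site), regulatory PM2.5 is
#' regressed on the raw sensor value, temperature, relative humidity,
#' uptime and operating time by weighted least squares, with Gaussian
#' spatial kernel weights `exp(-d^2 / (2 bw^2))` on the distance between
#' the anchor and each pair's sensor site. `bandwidthKm = "auto"` selects
#' the bandwidth by leave-one-station-out cross-validated RMSE over a
#' logarithmic ladder. A rank-deficient local design is refit with a
#' doubled kernel (up to 6 doublings) before failing with the anchor name.
#'
#' @param pairs Collocated pairs from [findCollocations()].
#' @param bandwidthKm Positive number (km) or `"auto"`.
#' @return A [GwrModel-class].
#' @export
fitGWR <- function(pairs, bandwidthKm = "auto") {
  if (!nrow(pairs)) stop("no collocated pairs to fit")
  pairs <- pairs[complete.cases(pairs[, c("aqsPm25", gwrCovariates)]), ]
  anchors <- unique(pairs[, c("paStationId", "paLon", "paLat")])
  anchors <- anchors[order(anchors$paStationId), ]
  names(anchors) <- c("paStationId", "lon", "lat")
  X <- gwrDesign(pairs)
  y <- pairs$aqsPm25
  pairKm <- function(lon, lat)
    greatCircleM(lon, lat, pairs$paLon, pairs$paLat) / 1000

  if (identical(bandwidthKm, "auto")) {
    stations <- anchors$paStationId
    if (length(stations) < 2) {
      bandwidthKm <- 100
    } else {
      ladder <- exp(seq(log(2), log(300), length.out = 8))
      cvRmse <- vapply(ladder, function(bw) {
        se <- 0; n <- 0
        for (s in stations) {
          hold <- pairs$paStationId == s
          a <- anchors[anchors$paStationId == s, ]
          w <- exp(-0.5 * (pairKm(a$lon, a$lat) / bw)^2)
          w[hold] <- 0
          beta <- wlsOrNull(X, y, w)
          if (is.null(beta)) next
          pred <- X[hold, , drop = FALSE] %*% beta
          se <- se + sum((y[hold] - pred)^2); n <- n + sum(hold)
        }
        if (n == 0) Inf else sqrt(se / n)
      }, numeric(1))
      bandwidthKm <- ladder[which.min(cvRmse)]
    }
  }
  stopifnot(is.numeric(bandwidthKm), bandwidthKm > 0)

  coefs <- matrix(NA_real_, nrow(anchors), ncol(X),
                  dimnames = list(anchors$paStationId, colnames(X)))
  for (i in seq_len(nrow(anchors))) {
    dKm <- pairKm(anchors$lon[i], anchors$lat[i])
    bw <- bandwidthKm
    beta <- NULL
    for (try in 0:6) {
      beta <- wlsOrNull(X, y, exp(-0.5 * (dKm / bw)^2))
      if (!is.null(beta)) break
      bw <- bw * 2
    }
    if (is.null(beta))
      stop("singular local design at anchor ", anchors$paStationId[i])
    coefs[i, ] <- beta
  }
  new("GwrModel", anchors = anchors, coefficients = coefs,
      bandwidthKm = bandwidthKm, kernel = "gaussian")
}

# kernel-weighted anchor coefficients at arbitrary sites (rows of lon/lat)
localCoefficients <- function(model, lon, lat) {
  A <- nrow(model@anchors)
  out <- matrix(NA_real_, length(lon), ncol(model@coefficients),
                dimnames = list(NULL, colnames(model@coefficients)))
  for (i in seq_along(lon)) {
    dKm <- greatCircleM(lon[i], lat[i], model@anchors$lon,
                        model@anchors$lat) / 1000
    w <- exp(-0.5 * (dKm / model@bandwidthKm)^2)
    if (sum(w) < 1e-300) {        # far outside kernel reach: nearest anchor
      w <- rep(0, A); w[which.min(dKm)] <- 1
    }
    out[i, ] <- colSums(model@coefficients * (w / sum(w)))
  }
  out
}

#' Apply a geographically weighted calibration network-wide
#'
#' Every sensor receives a local coefficient vector interpolated as the
#' kernel-weighted average of the anchor coefficient vectors (a sensor far
#' outside kernel reach falls back to its nearest anchor). Calibrated
#' values are floored at 0 ug/m3; the raw value is retained in `pm25Raw`.
#' Rows missing any calibration covariate are dropped with a message.
#'
#' @param model A [GwrModel-class].
#' @param paObs Low-cost observations (schema of [sampleNetworks()]).
#' @return `paObs` with `pm25` replaced by the calibrated value and the
#'   raw value kept in `pm25Raw`.
#' @export
applyCalibration <- function(model, paObs) {
  stopifnot(is(model, "GwrModel"))
  covs <- c("pm25", "temperature", "relativeHumidity", "uptime",
            "operatingTime")
  ok <- complete.cases(paObs[, covs])
  if (any(!ok))
    message("applyCalibration: dropped ", sum(!ok),
            " row(s) with missing covariates")
  paObs <- paObs[ok, ]
  st <- unique(paObs[, c("stationId", "lon", "lat")])
  B <- localCoefficients(model, st$lon, st$lat)
  rownames(B) <- st$stationId
  Bo <- B[paObs$stationId, , drop = FALSE]
  X <- cbind(1, paObs$pm25, paObs$temperature, paObs$relativeHumidity,
             paObs$uptime, paObs$operatingTime)
  paObs$pm25Raw <- paObs$pm25
  paObs$pm25 <- pmax(0, rowSums(X * Bo))
  paObs
}
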