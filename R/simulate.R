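#' Construct a synthetic-domain configuration
#'
#' Returns a validated [DomainConfig-class] describing the synthetic smoke
#' episode: a 40 x 40 grid of 3 x 5 km cells observed for 120 hours by 30
#' sparse regulatory monitors (reporting ~25% of hours, i.e. ~6 reports per
#' station per day) and 240 clustered low-cost sensors (reporting nearly
#' every hour) whose raw values carry an additive +1.9 ug/m3 bias, a
#' humidity-dependent term and multiplicative error. A Gaussian smoke plume
#' advected by the domain wind rides on a log-normal background so that
#' roughly 2% of sampled ground observations are at or above 100 ug/m3.
#'
#' @param nx,ny Grid dimensions (cells).
#' @param cellDxKm,cellDyKm Cell size, km.
#' @param nHours Episode length, hours.
#' @param nAqs,nPurpleair Network sizes.
#' @param plumeAmplitude Peak plume PM2.5 (ug/m3).
#' @param plumeSigmaKm Plume spatial scale (km).
#' @param backgroundMean,backgroundSd Ambient PM2.5 mean/SD (ug/m3).
#' @param aqsReportProb,paReportProb Per-hour reporting probabilities.
#' @param aqsNoiseSd AQS measurement noise SD (ug/m3).
#' @param paBiasAdd,paBiasRhCoef,paBiasMult,paNoiseSd Low-cost sensor bias
#'   and noise parameters (see [DomainConfig-class]).
#' @param aodMissingFracBase Baseline AOD missingness probability.
#' @param aodSlope AOD per ug/m3 of PM2.5.
#' @param aodNoiseSd AOD noise SD.
#' @param rhMean Domain-mean relative humidity (percent).
#' @param smokeMaskThreshold Plume PM2.5 above which the smoke mask fires.
#' @param nPaClusters,paClusterSdKm Low-cost sensor clustering.
#' @param nCollocated Sensors placed within ~300 m of an AQS monitor.
#' @param originLon,originLat South-west corner of the grid (degrees).
#' @param seed Integer seed.
#' @return A [DomainConfig-class].
#' @examples
#' cfg <- domainConfig(nx = 10, ny = 10, nHours = 24,
#'                     nAqs = 5, nPurpleair = 20, seed = 7)
#' cfg
#' @export
domainConfig <- function(nx = 40, ny = 40, cellDxKm = 3, cellDyKm = 5,
                         nHours = 120, nAqs = 30, nPurpleair = 240,
                         plumeAmplitude = 170, plumeSigmaKm = 24,
                         backgroundMean = 9, backgroundSd = 5,
                         aqsReportProb = 0.25, paReportProb = 0.95,
                         aqsNoiseSd = 0.75,
                         paBiasAdd = 1.9, paBiasRhCoef = 0.04,
                         paBiasMult = 0.02, paNoiseSd = 2,
                         aodMissingFracBase = 0.35, aodSlope = 0.008,
                         aodNoiseSd = 0.05,
                         rhMean = 40, smokeMaskThreshold = 5,
                         nPaClusters = 20, paClusterSdKm = 2.5,
                         nCollocated = 30,
                         originLon = -121.8, originLat = 38.8,
                         seed = 1L) {
  new("DomainConfig",
      nx = as.integer(nx), ny = as.integer(ny),
      cellDxKm = cellDxKm, cellDyKm = cellDyKm,
      nHours = as.integer(nHours),
      nAqs = as.integer(nAqs), nPurpleair = as.integer(nPurpleair),
      plumeAmplitude = plumeAmplitude, plumeSigmaKm = plumeSigmaKm,
      backgroundMean = backgroundMean, backgroundSd = backgroundSd,
      aqsReportProb = aqsReportProb, paReportProb = paReportProb,
      aqsNoiseSd = aqsNoiseSd,
      paBiasAdd = paBiasAdd, paBiasRhCoef = paBiasRhCoef,
      paBiasMult = paBiasMult, paNoiseSd = paNoiseSd,
      aodMissingFracBase = aodMissingFracBase, aodSlope = aodSlope,
      aodNoiseSd = aodNoiseSd,
      rhMean = rhMean, smokeMaskThreshold = smokeMaskThreshold,
      nPaClusters = as.integer(nPaClusters),
      paClusterSdKm = paClusterSdKm,
      nCollocated = as.integer(nCollocated),
      originLon = originLon, originLat = originLat,
      seed = as.integer(seed))
}

#' Read / write a domain configuration as YAML
#'
#' @param path YAML file path.
#' @return `domainConfigFromYaml` returns a [DomainConfig-class];
#'   `domainConfigToYaml` writes `config` and returns `path` invisibly.
#' @export
domainConfigFromYaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(domainConfig, vals)
}

#' @rdname domainConfigFromYaml
#' @param config A [DomainConfig-class].
#' @export
domainConfigToYaml <- function(config, path) {
  nms <- slotNames("DomainConfig")
  vals <- lapply(nms, function(s) slot(config, s))
  names(vals) <- nms
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Generate the true PM2.5 field of a synthetic smoke episode
#'
#' The field is the sum of a strictly positive background (exponentiated
#' smooth Gaussian noise, so ambient PM2.5 is non-negative and right-skewed)
#' and a Gaussian plume whose center is advected each hour by the domain
#' wind (a simple Lagrangian track, reflected at the domain boundary) and
#' whose intensity ramps up over the first day with a diurnal modulation.
#' Identical configs (including seed) give bit-identical output.
#'
#' @param config A [DomainConfig-class].
#' @return A [FireDomain-class] with assays `background`, `plume` and
#'   `pm25_truth` (= background + plume), per-hour plume track and wind in
#'   `colData`, and cell geometry in `rowData`.
#' @export
simulateTruth <- function(config) {
  validObject(config)
  set.seed(config@seed)
  geom <- gridGeometry(config)
  nCell <- nrow(geom)
  H <- config@nHours

  # log-normal background: mean/sd on the natural scale
  s2 <- log(1 + (config@backgroundSd / config@backgroundMean)^2)
  mu <- log(config@backgroundMean) - s2 / 2
  spat <- smoothField(config@nx, config@ny, sigmaCells = 6)
  temp <- ar1Series(H, rho = 0.9, sdTot = 1)
  noise <- matrix(rnorm(nCell * H), nCell, H)
  z <- sqrt(0.3) * spat +
    sqrt(0.3) * matrix(temp, nCell, H, byrow = TRUE) +
    sqrt(0.4) * noise
  background <- exp(mu + sqrt(s2) * z)

  # wind and plume track (km coordinates; 1 m/s = 3.6 km/h)
  # steady easterly flow with a slow meridional oscillation, so the plume
  # sweeps the domain over the episode instead of hugging one latitude band
  windU <- -3 + ar1Series(H, rho = 0.85, sdTot = 0.8)
  windV <- 1.5 * sin(2 * pi * (seq_len(H) - 1) / 72) +
    ar1Series(H, rho = 0.85, sdTot = 0.5)
  Lx <- config@nx * config@cellDxKm
  Ly <- config@ny * config@cellDyKm
  px <- py <- numeric(H)
  px[1] <- 0.8 * Lx; py[1] <- 0.55 * Ly
  reflect <- function(x, L) {
    x <- x %% (2 * L)
    ifelse(x > L, 2 * L - x, x)
  }
  for (t in seq_len(H)[-1]) {
    px[t] <- reflect(px[t - 1] + windU[t - 1] * 3.6, Lx)
    py[t] <- reflect(py[t - 1] + windV[t - 1] * 3.6, Ly)
  }

  intensity <- pmin(seq_len(H) / 24, 1) *
    (0.75 + 0.25 * sin(2 * pi * ((seq_len(H) - 1) %% 24) / 24))
  d2 <- outer(geom$xKm, px, "-")^2 + outer(geom$yKm, py, "-")^2
  plume <- config@plumeAmplitude *
    matrix(intensity, nCell, H, byrow = TRUE) *
    exp(-d2 / (2 * config@plumeSigmaKm^2))

  pm25 <- background + plume
  hourNames <- paste0("h", seq_len(H) - 1L)
  mk <- function(m) { dimnames(m) <- list(NULL, hourNames); m }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(background = mk(background), plume = mk(plume),
                  pm25_truth = mk(pm25)),
    rowData = S4Vectors::DataFrame(geom),
    colData = S4Vectors::DataFrame(
      hour = seq_len(H) - 1L, plumeX = px, plumeY = py,
      windU = windU, windV = windV, intensity = intensity,
      row.names = hourNames),
    metadata = list(config = config)
  )
  new("FireDomain", se)
}

#' Simulate gridded satellite, meteorology and static predictors
#'
#' Adds to a truth-only domain: AOD proportional to true PM2.5 with noise
#' and retrieval failure whose probability increases with PM2.5 (emulating
#' failed retrievals inside thick smoke), binary smoke/dust/aerosol masks,
#' six meteorology fields (2-m temperature K, surface pressure Pa, 10-m
#' u/v wind m/s consistent with the plume-advecting wind, boundary-layer
#' height m, relative humidity %), and static per-cell covariates
#' (elevation, four land-use fractions, distance to nearest road).
#'
#' @param config A [DomainConfig-class] (the one that built `domain`).
#' @param domain A [FireDomain-class] from [simulateTruth()].
#' @return `domain` with predictor assays and static `rowData` columns.
#' @export
simulatePredictors <- function(config, domain) {
  validObject(config)
  set.seed(config@seed + 1000003L)
  nCell <- nrow(domain); H <- ncol(domain)
  truth <- truthField(domain)
  plume <- plumeField(domain)
  cd <- SummarizedExperiment::colData(domain)
  hour0 <- cd$hour

  # --- static covariates -------------------------------------------------
  geom <- cellCenters(domain)
  elevRaw <- smoothField(config@nx, config@ny, 8)
  elevation <- 600 * (elevRaw - min(elevRaw)) / diff(range(elevRaw))
  lu <- vapply(1:4, function(i) smoothField(config@nx, config@ny, 5),
               numeric(nCell))
  elu <- exp(1.2 * lu)
  lu <- elu / rowSums(elu)
  nRoads <- 8L
  roadX <- runif(nRoads, 0, config@nx * config@cellDxKm)
  roadY <- runif(nRoads, 0, config@ny * config@cellDyKm)
  roadDistKm <- apply(
    sqrt(outer(geom$xKm, roadX, "-")^2 + outer(geom$yKm, roadY, "-")^2),
    1, min)

  # --- satellite ---------------------------------------------------------
  aod <- pmax(config@aodSlope * truth +
                matrix(rnorm(nCell * H, sd = config@aodNoiseSd), nCell, H), 0)
  pMiss <- pmin(0.95, config@aodMissingFracBase + 0.5 * pmin(truth / 300, 1))
  aod[matrix(runif(nCell * H), nCell, H) < pMiss] <- NA_real_
  smokeMask <- (plume > config@smokeMaskThreshold) * 1
  dustMask <- matrix(rbinom(nCell * H, 1, 0.02), nCell, H)
  aerosolMask <- pmax(smokeMask, dustMask, (truth > 60) * 1)

  # --- meteorology -------------------------------------------------------
  diurnal <- sin(2 * pi * (hour0 - 8) / 24)   # peaks mid-afternoon
  sT <- smoothField(config@nx, config@ny, 6)
  t2m <- 288 + 3 * sT - 0.006 * elevation +
    matrix(5 * diurnal + ar1Series(H, 0.9, 1.5), nCell, H, byrow = TRUE) +
    matrix(rnorm(nCell * H, sd = 0.5), nCell, H)
  pressure <- 101325 - 11.3 * elevation +
    matrix(250 * ar1Series(H, 0.95, 1), nCell, H, byrow = TRUE) +
    matrix(rnorm(nCell * H, sd = 25), nCell, H)
  sU <- smoothField(config@nx, config@ny, 6)
  sV <- smoothField(config@nx, config@ny, 6)
  u10 <- matrix(cd$windU, nCell, H, byrow = TRUE) + 0.6 * sU +
    matrix(rnorm(nCell * H, sd = 0.3), nCell, H)
  v10 <- matrix(cd$windV, nCell, H, byrow = TRUE) + 0.6 * sV +
    matrix(rnorm(nCell * H, sd = 0.3), nCell, H)
  sP <- smoothField(config@nx, config@ny, 6)
  pblh <- pmax(700 + 80 * sP +
                 matrix(450 * diurnal + 120 * ar1Series(H, 0.85, 1),
                        nCell, H, byrow = TRUE) +
                 matrix(rnorm(nCell * H, sd = 30), nCell, H), 50)
  sR <- smoothField(config@nx, config@ny, 6)
  rh <- pmin(pmax(config@rhMean - 12 *
                    matrix(diurnal, nCell, H, byrow = TRUE) +
                    6 * sR +
                    matrix(3 * ar1Series(H, 0.9, 1), nCell, H, byrow = TRUE) +
                    matrix(rnorm(nCell * H, sd = 1.5), nCell, H), 5), 100)

  hourNames <- colnames(domain)
  mk <- function(m) { dimnames(m) <- list(NULL, hourNames); m }
  SummarizedExperiment::assays(domain) <- c(
    SummarizedExperiment::assays(domain),
    list(aod = mk(aod), smoke_mask = mk(smokeMask),
         dust_mask = mk(dustMask), aerosol_mask = mk(aerosolMask),
         t2m = mk(t2m), pressure = mk(pressure),
         u10 = mk(u10), v10 = mk(v10), pblh = mk(pblh), rh = mk(rh)))
  rd <- SummarizedExperiment::rowData(domain)
  rd$elevation <- elevation
  rd$developedFrac <- lu[, 1]
  rd$forestFrac <- lu[, 2]
  rd$shrubFrac <- lu[, 3]
  rd$herbFrac <- lu[, 4]
  rd$roadDistKm <- roadDistKm
  SummarizedExperiment::rowData(domain) <- rd
  domain
}

#' Generate a full synthetic domain (truth plus predictors)
#'
#' @param config A [DomainConfig-class].
#' @return A [FireDomain-class] with truth and all predictor assays.
#' @examples
#' dom <- simulateDomain(domainConfig(nx = 12, ny = 12, nHours = 24,
#'                                    nAqs = 4, nPurpleair = 24,
#'                                    nPaClusters = 4, nCollocated = 4,
#'                                    seed = 1))
#' dom
#' @export
simulateDomain <- function(config) {
  simulatePredictors(config, simulateTruth(config))
}

#' Sample ground observations from both monitoring networks
#'
#' Places `nAqs` regulatory monitors quasi-uniformly (evenly spaced along a
#' Hilbert ordering of the grid, jittered within their cell) and
#' `nPurpleair` low-cost sensors in spatial clusters, with the first
#' `nCollocated` sensors sited within ~300 m of an AQS monitor so that
#' calibration pairs exist. Monitors report each hour with their network's
#' reporting probability. AQS values are truth plus small zero-mean noise;
#' raw low-cost values follow
#' `truth * (1 + paBiasMult) + paBiasAdd + paBiasRhCoef * (RH - rhMean) +
#' noise`, floored at 0, and carry sensor temperature, relative humidity,
#' uptime and operating-time covariates.
#'
#' @param config A [DomainConfig-class].
#' @param domain The matching [FireDomain-class] (with predictors, so that
#'   sensor RH/temperature can be sampled from the gridded fields).
#' @return data.frame, one row per report: `stationId`, `network`
#'   ("AQS"/"PURPLEAIR"), `lon`, `lat`, `hour` (0-based), `pm25`,
#'   `temperature` (degC), `relativeHumidity` (%), `uptime` (h),
#'   `operatingTime` (days), `cellId`, `truthPm25`.
#' @export
sampleNetworks <- function(config, domain) {
  validObject(config)
  if (config@nAqs + config@nPurpleair > config@nx * config@ny)
    stop("more stations than grid cells")
  set.seed(config@seed + 2000003L)
  geom <- cellCenters(domain)
  H <- config@nHours
  truth <- truthField(domain)
  rhF <- SummarizedExperiment::assay(domain, "rh")
  t2mF <- SummarizedExperiment::assay(domain, "t2m")

  # AQS: evenly spaced along a Hilbert ordering of cells, jittered in-cell
  hx <- floor(255 * geom$xKm / max(geom$xKm))
  hy <- floor(255 * geom$yKm / max(geom$yKm))
  ord <- order(hilbertIndex(hx, hy, 8L), geom$cellId)
  pick <- ord[round(seq(1, length(ord), length.out = config@nAqs + 2))[
    seq_len(config@nAqs) + 1L]]
  aqsX <- geom$xKm[pick] + runif(config@nAqs, -0.4, 0.4) * config@cellDxKm
  aqsY <- geom$yKm[pick] + runif(config@nAqs, -0.4, 0.4) * config@cellDyKm

  # PurpleAir: collocated subset near AQS sites, remainder in clusters
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  Lx <- config@nx * config@cellDxKm; Ly <- config@ny * config@cellDyKm
  nPa <- config@nPurpleair
  nCol <- min(config@nCollocated, nPa)
  colIdx <- rep(seq_len(config@nAqs), length.out = nCol)
  paX <- paY <- numeric(nPa)
  paX[seq_len(nCol)] <- aqsX[colIdx] + rnorm(nCol, sd = 0.12)
  paY[seq_len(nCol)] <- aqsY[colIdx] + rnorm(nCol, sd = 0.12)
  if (nPa > nCol) {
    # cluster centers concentrate along the smoke corridor (the dense
    # sensor metros sit downwind of the fire), with a uniform tail so some
    # clusters stay outside the plume's reach
    cx <- runif(config@nPaClusters, 0.05 * Lx, 0.95 * Lx)
    cy <- ifelse(runif(config@nPaClusters) < 0.6,
                 clamp(rnorm(config@nPaClusters, 0.55 * Ly, 0.12 * Ly),
                       0.05 * Ly, 0.95 * Ly),
                 runif(config@nPaClusters, 0.05 * Ly, 0.95 * Ly))
    cl <- rep(seq_len(config@nPaClusters), length.out = nPa - nCol)
    paX[(nCol + 1):nPa] <- cx[cl] + rnorm(nPa - nCol, sd = config@paClusterSdKm)
    paY[(nCol + 1):nPa] <- cy[cl] + rnorm(nPa - nCol, sd = config@paClusterSdKm)
  }
  paX <- clamp(paX, 0.01 * Lx, 0.99 * Lx); paY <- clamp(paY, 0.01 * Ly, 0.99 * Ly)

  toObs <- function(xKm, yKm, ids, network) {
    lon <- kmToLon(xKm, config@originLon, config@originLat)
    lat <- kmToLat(yKm, config@originLat)
    cell <- lonLatToCell(lon, lat, config)
    n <- length(ids)
    data.frame(stationId = rep(ids, each = H),
               network = network,
               lon = rep(lon, each = H), lat = rep(lat, each = H),
               hour = rep(seq_len(H) - 1L, times = n),
               cellId = rep(cell, each = H))
  }
  aqsIds <- sprintf("AQS_%02d", seq_len(config@nAqs))
  paIds <- sprintf("PA_%03d", seq_len(nPa))

  aqs <- toObs(aqsX, aqsY, aqsIds, "AQS")
  aqs$truthPm25 <- truth[cbind(aqs$cellId + 1L, aqs$hour + 1L)]
  aqsReport <- runif(nrow(aqs)) < config@aqsReportProb
  aqs$pm25 <- pmax(0, aqs$truthPm25 + rnorm(nrow(aqs), sd = config@aqsNoiseSd))
  aqs$temperature <- NA_real_
  aqs$relativeHumidity <- NA_real_
  aqs$uptime <- NA_real_
  aqs$operatingTime <- NA_real_
  aqs <- aqs[aqsReport, ]

  pa <- toObs(paX, paY, paIds, "PURPLEAIR")
  pa$truthPm25 <- truth[cbind(pa$cellId + 1L, pa$hour + 1L)]
  paReport <- runif(nrow(pa)) < config@paReportProb
  pa$relativeHumidity <- clamp(
    rhF[cbind(pa$cellId + 1L, pa$hour + 1L)] + rnorm(nrow(pa), sd = 2), 1, 100)
  pa$temperature <- t2mF[cbind(pa$cellId + 1L, pa$hour + 1L)] - 273.15 +
    rnorm(nrow(pa), sd = 0.7)
  # uptime: hours since last reboot (reboots ~1%/h); operating time in days
  reboot <- matrix(runif(nPa * H) < 0.01, nPa, H)
  up0 <- floor(runif(nPa, 0, 500))
  uptime <- matrix(0, nPa, H)
  uptime[, 1] <- up0
  for (t in seq_len(H)[-1])
    uptime[, t] <- ifelse(reboot[, t], 0, uptime[, t - 1] + 1)
  opt0 <- runif(nPa, 30, 400)
  pa$uptime <- uptime[cbind(match(pa$stationId, paIds), pa$hour + 1L)]
  pa$operatingTime <- opt0[match(pa$stationId, paIds)] + pa$hour / 24
  pa$pm25 <- pmax(0, pa$truthPm25 * (1 + config@paBiasMult) +
                    config@paBiasAdd +
                    config@paBiasRhCoef * (pa$relativeHumidity - config@rhMean) +
                    rnorm(nrow(pa), sd = config@paNoiseSd))
  pa <- pa[paReport, ]

  cols <- c("stationId", "network", "lon", "lat", "hour", "pm25",
            "temperature", "relativeHumidity", "uptime", "operatingTime",
            "cellId", "truthPm25")
  out <- rbind(aqs[, cols], pa[, cols])
  rownames(out) <- NULL
  out
}

#' Write ground observations / gridded predictors to CSV
#'
#' `writeObservationsCsv` writes one row per observation with the stable
#' column schema of [sampleNetworks()]. `writeGridCsv` writes one row per
#' cell-hour with all assay values and static covariates.
#'
#' @param obs Observation data.frame.
#' @param domain A [FireDomain-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeObservationsCsv <- function(obs, path) {
  write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeObservationsCsv
#' @export
writeGridCsv <- function(domain, path) {
  an <- SummarizedExperiment::assayNames(domain)
  nCell <- nrow(domain); H <- ncol(domain)
  out <- data.frame(cellId = rep(seq_len(nCell) - 1L, times = H),
                    hour = rep(seq_len(H) - 1L, each = nCell))
  for (a in an)
    out[[a]] <- as.vector(SummarizedExperiment::assay(domain, a))
  rd <- as.data.frame(SummarizedExperiment::rowData(domain))
  statics <- setdiff(colnames(rd), c("cellId"))
  for (s in statics) out[[s]] <- rep(rd[[s]], times = H)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
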