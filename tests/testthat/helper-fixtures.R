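# Small domain used by unit tests; the acceptance suite exercises the
# default-scale configuration.
tinyConfig <- function(seed = 1, ...) {
  domainConfig(nx = 12, ny = 12, nHours = 24, nAqs = 5, nPurpleair = 30,
               nPaClusters = 5, nCollocated = 5, seed = seed, ...)
}

# lon/lat a given number of meters north / east of a reference point
ptNorth <- function(lon, lat, meters) c(lon, lat + meters / 110574)
ptEast <- function(lon, lat, meters) {
  c(lon + meters / (111320 * cos(lat * pi / 180)), lat)
}

# one observation row in the sampleNetworks() schema
obsRow <- function(stationId, network, lon, lat, hour, pm25,
                   temperature = 15, relativeHumidity = 40,
                   uptime = 100, operatingTime = 200) {
  data.frame(stationId = stationId, network = network, lon = lon, lat = lat,
             hour = as.integer(hour), pm25 = pm25,
             temperature = temperature,
             relativeHumidity = relativeHumidity,
             uptime = uptime, operatingTime = operatingTime,
             cellId = 0L, truthPm25 = NA_real_)
}

# ---- independent oracles --------------------------------------------------

# brute-force IDW neighbor layer: all-pairs great-circle scan
bruteIdw <- function(targets, ground, domain, k = 5, selfExclude = TRUE) {
  geom <- cellCenters(domain)
  lonOf <- function(id) geom$lon[match(id, geom$cellId)]
  latOf <- function(id) geom$lat[match(id, geom$cellId)]
  vapply(seq_len(nrow(targets)), function(i) {
    g <- ground[ground$hour == targets$hour[i], ]
    if (selfExclude) g <- g[g$cellId != targets$cellId[i], ]
    if (!nrow(g)) return(NA_real_)
    d <- geosphere::distHaversine(
      cbind(lonOf(targets$cellId[i]), latOf(targets$cellId[i])),
      cbind(lonOf(g$cellId), latOf(g$cellId)))
    o <- order(d, g$cellId)
    use <- o[seq_len(min(k, length(o)))]
    if (any(d[use] == 0)) return(g$pm25[use][which(d[use] == 0)[1]])
    sum(g$pm25[use] / d[use]) / sum(1 / d[use])
  }, numeric(1))
}

# brute-force SMOTE honouring the documented RNG contract but with its own
# k-NN search and interpolation arithmetic
bruteSmote <- function(rows, config, continuousCols, binaryCols,
                       targetCol = "pm25") {
  rows$isSynthetic <- FALSE
  minority <- which(rows[[targetCol]] >= config$minorityCutoff)
  m <- length(minority)
  k <- min(config$kNeighbors, m - 1L)
  M <- as.matrix(rows[minority, continuousCols, drop = FALSE])
  if (config$standardize) {
    mu <- colMeans(M); sdv <- apply(M, 2, sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    M <- sweep(sweep(M, 2, mu), 2, sdv, "/")
  }
  nnOf <- function(i) {
    d <- sqrt(colSums((t(M) - M[i, ])^2))
    d[i] <- Inf
    order(d)[seq_len(k)]
  }
  nS <- config$nSynthPerMinority
  set.seed(config$seed)
  nbPick <- sample.int(k, m * nS, replace = TRUE)
  g <- runif(m * nS)
  out <- rows
  idx <- 0L
  interp <- c(continuousCols, targetCol)
  for (i in seq_len(m)) {
    nn <- nnOf(i)
    for (j in seq_len(nS)) {
      idx <- idx + 1L
      seedRow <- rows[minority[i], , drop = FALSE]
      nbRow <- rows[minority[nn[nbPick[idx]]], , drop = FALSE]
      newRow <- seedRow
      for (cc in interp)
        newRow[[cc]] <- seedRow[[cc]] + g[idx] * (nbRow[[cc]] - seedRow[[cc]])
      newRow$isSynthetic <- TRUE
      out <- rbind(out, newRow)
    }
  }
  rownames(out) <- NULL
  out
}

# exhaustive injective point->cell assignment minimising total distance
bruteAssign <- function(metPoints, cells) {
  np <- nrow(metPoints); nc <- nrow(cells)
  d <- outer(seq_len(np), seq_len(nc), function(i, j)
    geosphere::distHaversine(cbind(metPoints$lon[i], metPoints$lat[i]),
                             cbind(cells$lon[j], cells$lat[j])))
  if (np <= nc) {
    perms <- gtoolsPerms(nc, np)      # ordered selections of cells
    best <- NULL; bestD <- Inf
    for (r in seq_len(nrow(perms))) {
      tot <- sum(d[cbind(seq_len(np), perms[r, ])])
      if (tot < bestD) { bestD <- tot; best <- perms[r, ] }
    }
    list(cellOfPoint = best, total = bestD)
  } else {
    perms <- gtoolsPerms(np, nc)      # ordered selections of points
    best <- NULL; bestD <- Inf
    for (r in seq_len(nrow(perms))) {
      tot <- sum(d[cbind(perms[r, ], seq_len(nc))])
      if (tot < bestD) { bestD <- tot; best <- perms[r, ] }
    }
    list(pointOfCell = best, total = bestD)
  }
}

# all ordered selections of size r from n items (small n only)
gtoolsPerms <- function(n, r) {
  if (r == 1) return(matrix(seq_len(n), ncol = 1))
  sub <- gtoolsPerms(n, r - 1)
  out <- NULL
  for (i in seq_len(n)) {
    keep <- sub[rowSums(sub == i) == 0, , drop = FALSE]
    out <- rbind(out, cbind(i, keep))
  }
  unname(out)
}

# feature-table-like random rows for SMOTE tests
randomFeatureRows <- function(n, seed, minorityFrac = 0.1,
                              contCols = c("x1", "x2", "x3"),
                              binCols = c("b1")) {
  set.seed(seed)
  out <- data.frame(cellId = sample(0:50, n, TRUE),
                    hour = sample(0:23, n, TRUE),
                    stationId = sprintf("S%03d", sample(1:40, n, TRUE)),
                    network = sample(c("AQS", "PURPLEAIR"), n, TRUE),
                    weight = sample(c(1, 0.15), n, TRUE))
  for (cc in contCols) out[[cc]] <- rnorm(n)
  for (bb in binCols) out[[bb]] <- rbinom(n, 1, 0.3)
  minor <- runif(n) < minorityFrac
  out$pm25 <- ifelse(minor, runif(n, 100, 400), runif(n, 0, 99))
  out
}
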