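# Geometry helpers: equirectangular lon/lat grid, great-circle distances,
# Hilbert ordering. Cell ids are 0-based, cellId = gridRow * nx + gridCol.

KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON_EQ <- 111.320

#' Great-circle distance in meters
#'
#' Haversine distance between points given as lon/lat degrees. Thin wrapper
#' around [geosphere::distHaversine()] used consistently for every distance
#' in the package (collocation, kernels, IDW, nearest-neighbor joins).
#'
#' @param lon1,lat1,lon2,lat2 Coordinate vectors (degrees), recycled.
#' @return Distances in meters.
#' @export
greatCircleM <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

# lon/lat <-> local km coordinates (equirectangular about the grid origin)
kmToLon <- function(xKm, originLon, originLat) {
  originLon + xKm / (KM_PER_DEG_LON_EQ * cos(originLat * pi / 180))
}
kmToLat <- function(yKm, originLat) originLat + yKm / KM_PER_DEG_LAT
lonToKm <- function(lon, originLon, originLat) {
  (lon - originLon) * KM_PER_DEG_LON_EQ * cos(originLat * pi / 180)
}
latToKm <- function(lat, originLat) (lat - originLat) * KM_PER_DEG_LAT

# cell centers for a config; cellId-ordered data.frame
gridGeometry <- function(config) {
  nx <- config@nx; ny <- config@ny
  gridCol <- rep(seq_len(nx) - 1L, times = ny)
  gridRow <- rep(seq_len(ny) - 1L, each = nx)
  xKm <- (gridCol + 0.5) * config@cellDxKm
  yKm <- (gridRow + 0.5) * config@cellDyKm
  data.frame(
    cellId = gridRow * nx + gridCol,
    gridCol = gridCol, gridRow = gridRow,
    xKm = xKm, yKm = yKm,
    lon = kmToLon(xKm, config@originLon, config@originLat),
    lat = kmToLat(yKm, config@originLat)
  )
}

# map lon/lat to containing cell id (clamped to the grid)
lonLatToCell <- function(lon, lat, config) {
  xKm <- lonToKm(lon, config@originLon, config@originLat)
  yKm <- latToKm(lat, config@originLat)
  col <- pmin(pmax(floor(xKm / config@cellDxKm), 0), config@nx - 1L)
  row <- pmin(pmax(floor(yKm / config@cellDyKm), 0), config@ny - 1L)
  as.integer(row * config@nx + col)
}

# Hilbert curve index of integer coordinates (x, y) in [0, 2^order).
# Standard xy->d bit-interleaving walk; used to order monitors so that
# round-robin dealing yields spatially heterogeneous groups.
hilbertIndex <- function(x, y, order = 8L) {
  stopifnot(all(x >= 0), all(y >= 0),
            all(x < 2^order), all(y < 2^order))
  one <- function(xi, yi) {
    d <- 0
    s <- bitwShiftL(1L, order - 1L)
    while (s > 0L) {
      rx <- as.integer(bitwAnd(xi, s) > 0L)
      ry <- as.integer(bitwAnd(yi, s) > 0L)
      d <- d + s * s * bitwXor(3L * rx, ry)
      if (ry == 0L) {
        if (rx == 1L) {
          xi <- s - 1L - xi
          yi <- s - 1L - yi
        }
        tmp <- xi; xi <- yi; yi <- tmp
      }
      s <- s %/% 2L
    }
    d
  }
  mapply(one, as.integer(x), as.integer(y))
}

# smooth standardized 2-D Gaussian random field on an ny x nx grid,
# returned as a cellId-ordered vector (sd ~ 1, mean ~ 0)
smoothField <- function(nx, ny, sigmaCells) {
  z <- matrix(rnorm(nx * ny), nrow = ny, ncol = nx)
  sm <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sigmaCells)^2)
    k / rowSums(k)
  }
  f <- sm(ny) %*% z %*% t(sm(nx))
  f <- (f - mean(f)) / sd(f)
  as.vector(t(f))  # row-major: col fastest = cellId order
}

# first-order autoregressive series of length n, marginal sd ~ sdTot
ar1Series <- function(n, rho = 0.8, sdTot = 1) {
  e <- rnorm(n, sd = sdTot * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sdTot)
  for (t in seq_len(n)[-1]) x[t] <- rho * x[t - 1] + e[t]
  x
}
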