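#' Predict an hourly PM2.5 surface
#'
#' Assembles prediction-mode features for every grid cell at hour `h`
#' (the IDW neighbor layer uses all same-hour ground measurements), applies
#' the fitted forest to the complete cells, floors predictions at 0 and
#' leaves `NA` where any predictor is missing.
#'
#' @param forest A `ForestFit` from [trainForest()].
#' @param domain A [FireDomain-class] with predictors.
#' @param ground Deduplicated ground values ([dedupGround()] schema).
#' @param hour Hour index (0-based).
#' @param k Neighbors for the IDW layer.
#' @return A [PredictionSurface-class]. Warns and returns an all-`NA`
#'   surface when no cell is complete.
#' @export
predictHour <- function(forest, domain, ground, hour, k = 5) {
  cfg <- domainConfigOf(domain)
  ft <- assembleFeatures(domain, ground, mode = "prediction",
                         hours = hour, k = k)
  values <- rep(NA_real_, nrow(ft))
  if (!any(ft$complete)) {
    warning("no complete cells at hour ", hour, "; empty surface")
  } else {
    idx <- which(ft$complete)
    values[idx] <- pmax(0, predictForest(forest, ft[idx, , drop = FALSE]))
  }
  geom <- cellCenters(domain)
  new("PredictionSurface", hour = as.integer(hour), values = values,
      nx = cfg@nx, ny = cfg@ny, lon = geom$lon, lat = geom$lat,
      provenance = list(variant = forest$config$variant,
                        seed = forest$config$seed,
                        configHash = sum(utf8ToInt(paste(
                          format(cfg@seed), cfg@nx, cfg@ny, sep = ":")))))
}

#' Export / re-import an hourly prediction surface
#'
#' `"csv"` writes one row per cell (`cellId`, `lon`, `lat`, `hour`,
#' `pm25`); `"asc"` writes a georeferenced ESRI/GDAL ASCII grid (AAIGrid
#' with `dx`/`dy` keywords, since the cells are not square) with a WGS84
#' `.prj` sidecar and missing cells encoded as the declared `NODATA_value`.
#' Re-export of identical inputs is bit-identical. `readSurfaceAsc` reads
#' an `"asc"` export back (nodata decoded to `NA`).
#'
#' @param surface A [PredictionSurface-class].
#' @param path Output file path (`.csv` or `.asc`).
#' @param format `"csv"` or `"asc"`.
#' @param nodata Nodata value for `"asc"` (default -9999).
#' @return `path`, invisibly.
#' @export
exportSurface <- function(surface, path, format = c("csv", "asc"),
                          nodata = -9999) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(cellId = seq_along(surface@values) - 1L,
                     lon = surface@lon, lat = surface@lat,
                     hour = surface@hour, pm25 = surface@values)
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  m <- surfaceMatrix(surface)              # row 1 = southernmost
  m[is.na(m)] <- nodata
  dLon <- diff(sort(unique(surface@lon)))[1]
  dLat <- diff(sort(unique(surface@lat)))[1]
  hdr <- c(
    paste("ncols", surface@nx),
    paste("nrows", surface@ny),
    paste("xllcorner", format(min(surface@lon) - dLon / 2, digits = 12)),
    paste("yllcorner", format(min(surface@lat) - dLat / 2, digits = 12)),
    paste("dx", format(dLon, digits = 12)),
    paste("dy", format(dLat, digits = 12)),
    paste("NODATA_value", nodata))
  # ASCII grids run north to south
  body <- apply(m[rev(seq_len(surface@ny)), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 8),
                                  collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(paste0(
    'GEOGCS["WGS 84",DATUM["WGS_1984",SPHEROID["WGS 84",6378137,',
    '298.257223563]],PRIMEM["Greenwich",0],UNIT["degree",0.0174532925199433]]'),
    sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' @rdname exportSurface
#' @return `readSurfaceAsc` returns a list: `values` (ny-by-nx matrix,
#'   row 1 = southernmost), `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#'   `dx`, `dy`, `nodata`.
#' @export
readSurfaceAsc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:7], "\\s+")
  vals <- setNames(as.numeric(vapply(hdr, `[`, character(1), 2)),
                   tolower(vapply(hdr, `[`, character(1), 1)))
  body <- do.call(rbind, lapply(lines[-(1:7)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  body[body == vals[["nodata_value"]]] <- NA_real_
  list(values = body[rev(seq_len(nrow(body))), , drop = FALSE],
       ncols = vals[["ncols"]], nrows = vals[["nrows"]],
       xllcorner = vals[["xllcorner"]], yllcorner = vals[["yllcorner"]],
       dx = vals[["dx"]], dy = vals[["dy"]],
       nodata = vals[["nodata_value"]])
}

#' Import a CSV surface export
#'
#' @param path CSV file written by [exportSurface()].
#' @return data.frame `cellId`, `lon`, `lat`, `hour`, `pm25`.
#' @export
readSurfaceCsv <- function(path) {
  read.csv(path)
}
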