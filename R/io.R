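## Plain-text input/output. Fields and rasters travel as CSV matrices with
## a JSON sidecar carrying the grid definition and metadata, so every
## artefact is diff-able and self-describing; districts are GeoJSON.

gridToList <- function(grid) {
  list(origin_x = grid@originX, origin_y = grid@originY,
       dx = grid@dx, dy = grid@dy, n_cols = grid@nCols,
       n_rows = grid@nRows, crs = grid@crs)
}

gridFromList <- function(gl) {
  GridSpec(gl$origin_x, gl$origin_y, gl$dx, gl$dy,
           nCols = gl$n_cols, nRows = gl$n_rows, crs = gl$crs)
}

#' Read a dispersion-model point mesh from CSV
#'
#' Expected columns: \code{x}, \code{y}, \code{pollutant},
#' \code{timestamp} (ISO-8601), \code{value}.
#'
#' @param path CSV file.
#' @return data.frame suitable for \code{\link{rasterizeMesh}}.
#' @export
readPointMesh <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("x", "y", "pollutant", "timestamp", "value")
  if (!all(need %in% names(df)))
    stop("mesh CSV ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("mesh CSV ", path, " is empty")
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df
}

#' Read a station table from CSV
#'
#' Expected columns: \code{id}, \code{type}, \code{x}, \code{y} and
#' optionally \code{inlet_height_m}.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readStations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "type", "x", "y")
  if (!all(need %in% names(df)))
    stop("station CSV ", path, " must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' Write / read a concentration or excess-risk field
#'
#' The CSV holds one row per grid cell (columns \code{row}, \code{col},
#' then one column per hour); \code{<path>.json} holds the grid,
#' pollutant, unit and time axis.
#'
#' @param field a \linkS4class{ConcentrationField} or
#'   \linkS4class{ARField}.
#' @param path CSV destination.
#' @return \code{readConcentrationField} returns the reconstructed object.
#' @export
writeConcentrationField <- function(field, path) {
  v <- fieldValues(field)
  cc <- cellCenters(gridSpec(field))
  df <- data.frame(row = cc$row, col = cc$col, v)
  names(df) <- c("row", "col", sprintf("h%04d", seq_len(ncol(v))))
  data.table::fwrite(df, path)
  meta <- list(grid = gridToList(gridSpec(field)),
               pollutant = pollutant(field),
               unit = if (is(field, "ConcentrationField"))
                 concUnit(field) else "percent",
               kind = if (is(field, "ARField")) "ar" else "concentration",
               time = format(fieldTime(field), "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeConcentrationField
#' @export
readConcentrationField <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- gridFromList(as.list(meta$grid))
  df <- as.data.frame(data.table::fread(path))
  v <- as.matrix(df[, -(1:2), drop = FALSE])
  tm <- as.POSIXct(meta$time, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  if (identical(meta$kind, "ar"))
    ARField(v, grid, tm, meta$pollutant)
  else
    ConcentrationField(v, grid, tm, meta$pollutant, meta$unit)
}

#' Write / read a population raster
#'
#' CSV matrix (nRows lines of nCols counts, row 1 = southernmost) plus a
#' JSON sidecar with the grid.
#'
#' @param pop a \linkS4class{PopulationRaster}.
#' @param path CSV destination.
#' @export
writePopulation <- function(pop, path) {
  data.table::fwrite(as.data.frame(pop@counts), path, col.names = FALSE)
  jsonlite::write_json(list(grid = gridToList(pop@grid)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePopulation
#' @export
readPopulation <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- gridFromList(as.list(meta$grid))
  m <- as.matrix(data.table::fread(path, header = FALSE))
  PopulationRaster(m, grid)
}

#' Write SF maps as a long-format CSV
#'
#' One row per (station, cell): \code{station_id}, \code{pollutant},
#' \code{period}, \code{row}, \code{col}, \code{sf}, \code{n_valid},
#' \code{band}.
#'
#' @param sfMaps list of \linkS4class{SFMap}s.
#' @param path CSV destination.
#' @param header character vector of comment lines (prefixed \code{#})
#'   written before the table, e.g. the run-config hash.
#' @export
writeSFMaps <- function(sfMaps, path, header = character()) {
  rows <- lapply(sfMaps, function(m) {
    cc <- cellCenters(m@grid)
    sf <- cellsFromMap(m@values)
    data.frame(station_id = m@stationId, pollutant = m@pollutant,
               period = m@period, row = cc$row, col = cc$col, sf = sf,
               n_valid = cellsFromMap(m@nValid),
               band = as.character(classifyBand(sf)),
               stringsAsFactors = FALSE)
  })
  writeTableWithHeader(do.call(rbind, rows), path, header)
}

writeTableWithHeader <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written with a comment header
#'
#' @param path CSV file whose leading \code{#} lines are skipped.
#' @return data.frame.
#' @export
readReportTable <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write district polygons as GeoJSON
#'
#' Inverse of \code{\link{readDistricts}}: each named ring set becomes a
#' Polygon feature with a \code{name} property.
#'
#' @param districts named list of polygon ring sets.
#' @param path GeoJSON destination.
#' @export
writeDistricts <- function(districts, path) {
  feats <- lapply(names(districts), function(nm) {
    rings <- lapply(districts[[nm]], function(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    list(type = "Feature", properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
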