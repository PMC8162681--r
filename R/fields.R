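#' Build a concentration field
#'
#' @param values numeric cell-by-hour matrix (cells in row-major grid order);
#'   \code{NA} marks missing cell-hours.
#' @param grid a \linkS4class{GridSpec}.
#' @param time POSIXct vector of hourly timestamps, one per column.
#' @param pollutant one of \code{"PM10"}, \code{"PM2.5"}, \code{"NO2"},
#'   \code{"O3"}.
#' @param unit \code{"ug/m3"} or \code{"ppb"}.
#' @return A \linkS4class{ConcentrationField}.
#' @export
ConcentrationField <- function(values, grid, time, pollutant,
                               unit = c("ug/m3", "ppb")) {
  unit <- match.arg(unit)
  pollutant <- match.arg(pollutant, POLLUTANTS)
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(time))
  cc <- cellCenters(grid)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(conc = unname(values)),
    rowData = S4Vectors::DataFrame(row = cc$row, col = cc$col),
    colData = S4Vectors::DataFrame(time = as.POSIXct(time, tz = "UTC"))
  )
  new("ConcentrationField", se, grid = grid, pollutant = pollutant,
      unit = unit)
}

#' Build an excess-risk field
#'
#' Usually produced by \code{\link{computeAR}} / \code{\link{computeARTotal}}
#' rather than called directly.
#'
#' @inheritParams ConcentrationField
#' @param pollutant pollutant name or \code{"total"}.
#' @return An \linkS4class{ARField} (values in percent).
#' @export
ARField <- function(values, grid, time, pollutant) {
  pollutant <- match.arg(pollutant, QUANTITIES)
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(time))
  cc <- cellCenters(grid)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ar = unname(values)),
    rowData = S4Vectors::DataFrame(row = cc$row, col = cc$col),
    colData = S4Vectors::DataFrame(time = as.POSIXct(time, tz = "UTC"))
  )
  new("ARField", se, grid = grid, pollutant = pollutant)
}

#' Build a population raster
#'
#' @param counts nRows-by-nCols matrix of persons per cell
#'   (\code{counts[row, col]}, row 1 at minimum y).
#' @param grid a \linkS4class{GridSpec}.
#' @return A \linkS4class{PopulationRaster}.
#' @export
PopulationRaster <- function(counts, grid) {
  new("PopulationRaster", grid = grid,
      counts = matrix(as.numeric(counts), nrow = grid@nRows))
}

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname accessors
#' @export
setGeneric("pollutant", function(x) standardGeneric("pollutant"))

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("fieldTime", function(x) standardGeneric("fieldTime"))

#' @rdname accessors
#' @export
setGeneric("concUnit", function(x) standardGeneric("concUnit"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Accessors for aqrep objects
#'
#' \code{gridSpec} returns the \linkS4class{GridSpec}; \code{pollutant} the
#' pollutant (or \code{"total"}); \code{fieldValues} the cell-by-hour matrix;
#' \code{fieldTime} the hourly timestamps; \code{concUnit} the concentration
#' unit; \code{mapValues} the nRows-by-nCols value matrix of a map-like
#' object.
#'
#' @param x an aqrep S4 object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("gridSpec", "ConcentrationField", function(x) x@grid)
#' @rdname accessors
setMethod("gridSpec", "ARField", function(x) x@grid)
#' @rdname accessors
setMethod("gridSpec", "PopulationRaster", function(x) x@grid)
#' @rdname accessors
setMethod("gridSpec", "SFMap", function(x) x@grid)
#' @rdname accessors
setMethod("gridSpec", "RepresentativenessMap", function(x) x@grid)

#' @rdname accessors
setMethod("pollutant", "ConcentrationField", function(x) x@pollutant)
#' @rdname accessors
setMethod("pollutant", "ARField", function(x) x@pollutant)
#' @rdname accessors
setMethod("pollutant", "SFMap", function(x) x@pollutant)
#' @rdname accessors
setMethod("pollutant", "RepresentativenessMap", function(x) x@pollutant)

#' @rdname accessors
setMethod("fieldValues", "ConcentrationField",
          function(x) SummarizedExperiment::assay(x, 1L))
#' @rdname accessors
setMethod("fieldValues", "ARField",
          function(x) SummarizedExperiment::assay(x, 1L))

#' @rdname accessors
setMethod("fieldTime", "ConcentrationField", function(x) x$time)
#' @rdname accessors
setMethod("fieldTime", "ARField", function(x) x$time)

#' @rdname accessors
setMethod("concUnit", "ConcentrationField", function(x) x@unit)

#' @rdname accessors
setMethod("mapValues", "SFMap", function(x) x@values)
#' @rdname accessors
setMethod("mapValues", "RepresentativenessMap", function(x) x@values)
#' @rdname accessors
setMethod("mapValues", "PopulationRaster", function(x) x@counts)

#' @rdname accessors
#' @export
stationId <- function(x) {
  stopifnot(is(x, "SFMap"))
  x@stationId
}

#' @rdname accessors
#' @export
periodLabel <- function(x) {
  stopifnot(is(x, "SFMap") || is(x, "RepresentativenessMap"))
  x@period
}

setMethod("show", "ConcentrationField", function(object) {
  v <- fieldValues(object)
  cat(sprintf("ConcentrationField: %s [%s], %d cells x %d hours\n",
              object@pollutant, object@unit, nrow(v), ncol(v)))
  cat(sprintf("  %.1f%% cell-hours present; range %s\n",
              100 * mean(!is.na(v)),
              if (all(is.na(v))) "all missing" else
                sprintf("[%.3g, %.3g]", min(v, na.rm = TRUE),
                        max(v, na.rm = TRUE))))
  show(object@grid)
})

setMethod("show", "ARField", function(object) {
  v <- fieldValues(object)
  cat(sprintf("ARField: %%AR %s, %d cells x %d hours, mean %.3g%%\n",
              object@pollutant, nrow(v), ncol(v), mean(v, na.rm = TRUE)))
  show(object@grid)
})

setMethod("show", "PopulationRaster", function(object) {
  cat(sprintf("PopulationRaster: %d x %d cells, total %.6g persons\n",
              object@grid@nRows, object@grid@nCols, sum(object@counts)))
})

setMethod("show", "SFMap", function(object) {
  cat(sprintf(
    "SFMap: station %s, %s, %s period; defined %.1f%%, mean SF %.3f\n",
    object@stationId, object@pollutant, object@period,
    100 * mean(!is.na(object@values)), mean(object@values, na.rm = TRUE)))
})

setMethod("show", "RepresentativenessMap", function(object) {
  cat(sprintf(
    "RepresentativenessMap: %s, %s period; defined %.1f%%, mean R %.3f\n",
    object@pollutant, object@period,
    100 * mean(!is.na(object@values)), mean(object@values, na.rm = TRUE)))
})
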