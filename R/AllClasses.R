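#' @import methods
#' @importFrom stats cor.test rnorm runif sd
#' @importFrom utils read.csv write.csv head
NULL

POLLUTANTS <- c("PM10", "PM2.5", "NO2", "O3")
QUANTITIES <- c(POLLUTANTS, "total")
UNITS <- c("ug/m3", "ppb")
STATION_TYPES <- c("general", "roadside", "background")
PERIODS <- c("annual", "spring", "summer", "autumn", "winter")

#' Analysis grid definition
#'
#' A regular raster grid in projected planar coordinates. Cells are
#' half-open rectangles \eqn{[x_0, x_0+dx) \times [y_0, y_0+dy)} so that every
#' point belongs to exactly one cell; a point on a shared edge belongs to the
#' lower/left cell. Rows are counted from the grid's minimum y (row 1 is the
#' southernmost row), columns from the minimum x.
#'
#' @slot originX,originY coordinates of the grid's lower-left corner (metres).
#' @slot dx,dy cell width and height in metres (defaults 45 and 48, the cell
#'   size used throughout the package's worked examples).
#' @slot nCols,nRows grid dimensions.
#' @slot crs identifier of the projected coordinate reference system. Only
#'   compared for equality; no reprojection is performed.
#' @exportClass GridSpec
setClass("GridSpec",
  representation(
    originX = "numeric", originY = "numeric",
    dx = "numeric", dy = "numeric",
    nCols = "integer", nRows = "integer",
    crs = "character"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@dx) != 1 || !is.finite(object@dx) || object@dx <= 0)
    msg <- c(msg, "dx must be a single positive number")
  if (length(object@dy) != 1 || !is.finite(object@dy) || object@dy <= 0)
    msg <- c(msg, "dy must be a single positive number")
  if (length(object@nCols) != 1 || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a positive integer")
  if (length(object@nRows) != 1 || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a positive integer")
  if (!all(is.finite(c(object@originX, object@originY))))
    msg <- c(msg, "grid origin must be finite")
  if (length(msg)) msg else TRUE
})

#' Hourly concentration field on the analysis grid
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"conc"} is a
#' cell-by-hour matrix for one pollutant. Rows are grid cells in row-major
#' order (cell \eqn{(r,c)} is row \eqn{(r-1)\cdot nCols + c}), with their
#' \code{row}/\code{col} indices in \code{rowData}; columns are hourly
#' timestamps carried in \code{colData$time}. Missing cell-hours (e.g. cells
#' that received no dispersion-model output points) are \code{NA}.
#'
#' @slot grid the \linkS4class{GridSpec} the field lives on.
#' @slot pollutant one of \code{"PM10"}, \code{"PM2.5"}, \code{"NO2"},
#'   \code{"O3"}.
#' @slot unit \code{"ug/m3"} or \code{"ppb"} (gases only).
#' @exportClass ConcentrationField
setClass("ConcentrationField",
  contains = "SummarizedExperiment",
  representation(grid = "GridSpec", pollutant = "character",
                 unit = "character")
)

setValidity("ConcentrationField", function(object) {
  msg <- character()
  if (!object@pollutant %in% POLLUTANTS)
    msg <- c(msg, sprintf("unknown pollutant '%s'", object@pollutant))
  if (!object@unit %in% UNITS)
    msg <- c(msg, sprintf("unknown unit '%s'", object@unit))
  if (object@unit == "ppb" && object@pollutant %in% c("PM10", "PM2.5"))
    msg <- c(msg, "particulate fields cannot be expressed in ppb")
  if (nrow(object) != nCells(object@grid))
    msg <- c(msg, "number of rows must equal the grid's cell count")
  v <- SummarizedExperiment::assay(object, 1L)
  if (any(v < 0, na.rm = TRUE))
    msg <- c(msg, "concentrations must be nonnegative where present")
  tm <- object$time
  if (is.null(tm) || !inherits(tm, "POSIXct"))
    msg <- c(msg, "colData$time must hold POSIXct timestamps")
  if (length(msg)) msg else TRUE
})

#' Excess hospital-admission risk field
#'
#' Cell-by-hour \%AR values (percent) for one pollutant, or for the combined
#' risk (\code{pollutant = "total"}: NO2 + O3 + the larger PM size fraction).
#' Same layout as \linkS4class{ConcentrationField}; masked (\code{NA})
#' wherever any contributing concentration was missing.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot pollutant a pollutant name or \code{"total"}.
#' @exportClass ARField
setClass("ARField",
  contains = "SummarizedExperiment",
  representation(grid = "GridSpec", pollutant = "character")
)

setValidity("ARField", function(object) {
  msg <- character()
  if (!object@pollutant %in% QUANTITIES)
    msg <- c(msg, sprintf("unknown pollutant/quantity '%s'", object@pollutant))
  if (nrow(object) != nCells(object@grid))
    msg <- c(msg, "number of rows must equal the grid's cell count")
  if (any(SummarizedExperiment::assay(object, 1L) < 0, na.rm = TRUE))
    msg <- c(msg, "%AR must be nonnegative where present")
  if (length(msg)) msg else TRUE
})

#' Gridded population counts
#'
#' Persons per grid cell, as an nRows-by-nCols matrix indexed
#' \code{counts[row, col]}.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot counts numeric matrix of nonnegative person counts.
#' @exportClass PopulationRaster
setClass("PopulationRaster",
  representation(grid = "GridSpec", counts = "matrix")
)

setValidity("PopulationRaster", function(object) {
  msg <- character()
  if (!identical(dim(object@counts),
                 c(object@grid@nRows, object@grid@nCols)))
    msg <- c(msg, "counts matrix dimensions must match the grid")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "population counts must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' Similarity-frequency map for one pseudo-station
#'
#' Per-cell similarity frequency of the cell's \%AR series against one
#' pseudo-station's series over one period, in \eqn{[0, 1]}; \code{NA} where
#' undefined (insufficient shared coverage). \code{nValid} records how many
#' timesteps entered each cell's comparison.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot stationId id of the reference station.
#' @slot pollutant pollutant name or \code{"total"}.
#' @slot period one of annual/spring/summer/autumn/winter.
#' @slot values nRows-by-nCols numeric matrix of SF values.
#' @slot nValid nRows-by-nCols integer matrix of compared-timestep counts.
#' @exportClass SFMap
setClass("SFMap",
  representation(grid = "GridSpec", stationId = "character",
                 pollutant = "character", period = "character",
                 values = "matrix", nValid = "matrix")
)

setValidity("SFMap", function(object) {
  msg <- character()
  dm <- c(object@grid@nRows, object@grid@nCols)
  if (!identical(dim(object@values), dm) || !identical(dim(object@nValid), dm))
    msg <- c(msg, "values and nValid must be nRows x nCols matrices")
  v <- object@values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    msg <- c(msg, "SF values must lie in [0, 1] where defined")
  if (length(msg)) msg else TRUE
})

#' Network representativeness map
#'
#' Per-cell representativeness R of the whole monitoring network for one
#' quantity and period: the maximum SF the cell attains against any
#' pseudo-station. \code{NA} where no station yields a defined SF.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot pollutant pollutant name or \code{"total"}.
#' @slot period period label.
#' @slot values nRows-by-nCols numeric matrix of R values in [0, 1].
#' @exportClass RepresentativenessMap
setClass("RepresentativenessMap",
  representation(grid = "GridSpec", pollutant = "character",
                 period = "character", values = "matrix")
)

setValidity("RepresentativenessMap", function(object) {
  dm <- c(object@grid@nRows, object@grid@nCols)
  if (!identical(dim(object@values), dm))
    return("values must be an nRows x nCols matrix")
  if (any(object@values < 0 | object@values > 1, na.rm = TRUE))
    return("R values must lie in [0, 1] where defined")
  TRUE
})
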