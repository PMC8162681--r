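#' Construct a grid definition
#'
#' @param originX,originY projected coordinates of the lower-left corner (m).
#' @param dx,dy cell size in metres.
#' @param nCols,nRows grid dimensions.
#' @param crs coordinate reference system identifier (checked for equality
#'   between inputs, never reprojected).
#' @return A \linkS4class{GridSpec}.
#' @examples
#' g <- GridSpec(0, 0, nCols = 10, nRows = 10)
#' cellArea(g)   # 2160 m^2
#' @export
GridSpec <- function(originX, originY, dx = 45, dy = 48,
                     nCols, nRows, crs = "EPSG:2326") {
  new("GridSpec", originX = as.numeric(originX), originY = as.numeric(originY),
      dx = as.numeric(dx), dy = as.numeric(dy),
      nCols = as.integer(nCols), nRows = as.integer(nRows),
      crs = as.character(crs))
}

#' @describeIn GridSpec total number of cells.
#' @param grid a \linkS4class{GridSpec}.
#' @export
nCells <- function(grid) as.integer(grid@nRows) * as.integer(grid@nCols)

#' @describeIn GridSpec area of one cell in square metres (dx * dy).
#' @export
cellArea <- function(grid) grid@dx * grid@dy

#' @describeIn GridSpec check that two grids are interchangeable (same
#'   geometry and CRS).
#' @param other a second \linkS4class{GridSpec}.
#' @export
sameGrid <- function(grid, other) {
  isTRUE(all.equal(grid@originX, other@originX)) &&
    isTRUE(all.equal(grid@originY, other@originY)) &&
    isTRUE(all.equal(grid@dx, other@dx)) &&
    isTRUE(all.equal(grid@dy, other@dy)) &&
    grid@nCols == other@nCols && grid@nRows == other@nRows &&
    grid@crs == other@crs
}

#' Map points to grid cells
#'
#' Returns the 1-based (row, col) index of the half-open cell containing each
#' point; a point exactly on a shared edge belongs to the lower/left cell.
#' Points outside the grid get \code{NA} indices.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param x,y projected point coordinates (metres), equal length.
#' @return data.frame with columns \code{row}, \code{col}, \code{cell}
#'   (row-major linear index) and logical \code{inside}.
#' @export
cellIndexOf <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    bad <- which(!is.finite(x) | !is.finite(y))[1L]
    stop("non-finite coordinate at point ", bad)
  }
  col <- floor((x - grid@originX) / grid@dx) + 1
  row <- floor((y - grid@originY) / grid@dy) + 1
  inside <- col >= 1 & col <= grid@nCols & row >= 1 & row <= grid@nRows
  col[!inside] <- NA_real_
  row[!inside] <- NA_real_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((row - 1) * grid@nCols + col),
             inside = inside)
}

#' Cell-centre coordinates
#'
#' @param grid a \linkS4class{GridSpec}.
#' @return data.frame with one row per cell in row-major order: \code{row},
#'   \code{col}, \code{x}, \code{y} (centre coordinates in metres).
#' @export
cellCenters <- function(grid) {
  row <- rep(seq_len(grid@nRows), each = grid@nCols)
  col <- rep(seq_len(grid@nCols), times = grid@nRows)
  data.frame(row = row, col = col,
             x = grid@originX + (col - 0.5) * grid@dx,
             y = grid@originY + (row - 0.5) * grid@dy)
}

## cell-vector (row-major, length nCells) <-> map matrix [row, col]
mapFromCells <- function(v, grid) {
  matrix(v, nrow = grid@nRows, ncol = grid@nCols, byrow = TRUE)
}

cellsFromMap <- function(m) as.vector(t(m))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g x %g m (%g m^2 each)\n",
              object@nRows, object@nCols, object@dx, object@dy,
              object@dx * object@dy))
  cat(sprintf("  origin (%g, %g), CRS %s\n",
              object@originX, object@originY, object@crs))
})
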