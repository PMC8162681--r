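## raster_grid module: mesh rasterization, pseudo-station location,
## population resampling.

#' Rasterize an irregular point mesh onto the analysis grid
#'
#' Urban dispersion models emit hourly values on a dynamic mesh of output
#' points that is denser near sources. Each grid cell's hourly value is set
#' to the arithmetic mean of all mesh points falling inside that cell; cells
#' containing no point are missing (\code{NA}) at all hours. By default no
#' interpolation or gap-filling is performed; \code{fillNearest = TRUE}
#' copies each empty cell's series from the nearest covered cell centre.
#'
#' @param mesh data.frame with columns \code{x}, \code{y} (projected metres),
#'   \code{pollutant}, \code{timestamp} (POSIXct or ISO-8601 character) and
#'   \code{value}.
#' @param grid a \linkS4class{GridSpec}.
#' @param pollutant which pollutant to rasterize.
#' @param unit unit tag for the resulting field.
#' @param fillNearest fill empty cells from the nearest covered cell
#'   (default off).
#' @return A \linkS4class{ConcentrationField}.
#' @export
rasterizeMesh <- function(mesh, grid, pollutant, unit = c("ug/m3", "ppb"),
                          fillNearest = FALSE) {
  unit <- match.arg(unit)
  pollutant <- match.arg(pollutant, POLLUTANTS)
  stopifnot(is.data.frame(mesh),
            all(c("x", "y", "pollutant", "timestamp", "value") %in%
                  names(mesh)))
  mesh <- mesh[mesh$pollutant == pollutant, , drop = FALSE]
  if (nrow(mesh) == 0L)
    stop("mesh contains no points for pollutant ", pollutant)
  idx <- cellIndexOf(grid, mesh$x, mesh$y)
  keep <- idx$inside
  if (!any(keep))
    stop("mesh has no in-domain points for pollutant ", pollutant)
  mesh <- mesh[keep, , drop = FALSE]
  cell <- idx$cell[keep]
  tm <- as.POSIXct(mesh$timestamp, tz = "UTC")
  timeAxis <- sort(unique(tm))
  tIdx <- match(tm, timeAxis)

  nc <- nCells(grid)
  nt <- length(timeAxis)
  sums <- matrix(0, nc, nt)
  cnts <- matrix(0L, nc, nt)
  ## accumulate point values per (cell, hour) via flat matrix index
  flat <- (tIdx - 1L) * nc + cell
  s <- rowsum(mesh$value, group = flat)
  k <- rowsum(rep(1L, length(flat)), group = flat)
  pos <- as.integer(rownames(s))
  sums[pos] <- s
  cnts[pos] <- k
  values <- sums / ifelse(cnts > 0L, cnts, NA_real_)

  if (fillNearest) {
    covered <- rowSums(cnts) > 0L
    if (any(!covered) && any(covered)) {
      cc <- cellCenters(grid)
      emp <- which(!covered); cov <- which(covered)
      for (i in emp) {
        d2 <- (cc$x[cov] - cc$x[i])^2 + (cc$y[cov] - cc$y[i])^2
        values[i, ] <- values[cov[which.min(d2)], ]
      }
    }
  }
  ConcentrationField(values, grid, timeAxis, pollutant, unit)
}

#' Locate monitoring stations on the grid (pseudo-stations)
#'
#' Intersects each fixed-site monitor's coordinates with the grid: the cell
#' containing a station becomes its pseudo-station, whose modelled series
#' stands in for the monitor in all similarity comparisons. Stations outside
#' the grid are dropped with a warning.
#'
#' @param stations data.frame with columns \code{id}, \code{type} (one of
#'   general/roadside/background), \code{x}, \code{y} and optionally
#'   \code{inlet_height_m} (metadata only).
#' @param grid a \linkS4class{GridSpec}.
#' @return The station table restricted to in-domain stations, with
#'   \code{row}, \code{col} and row-major \code{cell} columns added.
#' @export
locatePseudoStations <- function(stations, grid) {
  stopifnot(is.data.frame(stations),
            all(c("id", "type", "x", "y") %in% names(stations)))
  if (anyDuplicated(stations$id))
    stop("duplicate station ids: ",
         paste(unique(stations$id[duplicated(stations$id)]), collapse = ", "))
  if (!all(stations$type %in% STATION_TYPES))
    stop("unknown station type(s): ",
         paste(setdiff(stations$type, STATION_TYPES), collapse = ", "))
  idx <- cellIndexOf(grid, stations$x, stations$y)
  if (any(!idx$inside))
    warning("excluding out-of-domain station(s): ",
            paste(stations$id[!idx$inside], collapse = ", "))
  out <- cbind(stations, idx[c("row", "col", "cell")])
  out[idx$inside, , drop = FALSE]
}

#' Resample a coarse population raster onto the analysis grid
#'
#' Each fine cell is assigned to the coarse cell whose centre is nearest to
#' the fine cell's centre; the coarse cell's person count is then divided
#' equally among the fine cells assigned to it, so the domain population
#' total is conserved (a plain nearest-neighbour value copy would multiply
#' the total by the cell-area ratio).
#'
#' @param coarse a \linkS4class{PopulationRaster} on a (typically coarser)
#'   grid.
#' @param fineGrid target \linkS4class{GridSpec}; must share the CRS.
#' @return A \linkS4class{PopulationRaster} on \code{fineGrid}.
#' @export
resamplePopulation <- function(coarse, fineGrid) {
  stopifnot(is(coarse, "PopulationRaster"), is(fineGrid, "GridSpec"))
  cg <- coarse@grid
  if (cg@crs != fineGrid@crs)
    stop("coarse and fine grids use different CRS: ",
         cg@crs, " vs ", fineGrid@crs)
  ## bounding boxes must overlap
  cxr <- c(cg@originX, cg@originX + cg@nCols * cg@dx)
  cyr <- c(cg@originY, cg@originY + cg@nRows * cg@dy)
  fxr <- c(fineGrid@originX, fineGrid@originX + fineGrid@nCols * fineGrid@dx)
  fyr <- c(fineGrid@originY, fineGrid@originY + fineGrid@nRows * fineGrid@dy)
  if (cxr[2] <= fxr[1] || fxr[2] <= cxr[1] ||
      cyr[2] <= fyr[1] || fyr[2] <= cyr[1])
    stop("coarse and fine grid extents are disjoint")

  cc <- cellCenters(fineGrid)
  ## nearest coarse-centre index along each axis (clamped to the raster)
  nearIdx <- function(p, orig, d, n) pmin(pmax(round((p - orig) / d + 0.5), 1), n)
  ccol <- nearIdx(cc$x, cg@originX, cg@dx, cg@nCols)
  crow <- nearIdx(cc$y, cg@originY, cg@dy, cg@nRows)
  src <- (crow - 1L) * cg@nCols + ccol           # row-major coarse index
  mult <- tabulate(src, nbins = nCells(cg))
  coarseCells <- cellsFromMap(coarse@counts)
  fine <- coarseCells[src] / mult[src]
  PopulationRaster(mapFromCells(fine, fineGrid), fineGrid)
}
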