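## representativeness module: network max over stations, represented
## area/population, PHNI, seasons, districts, area-vs-population correlation.

#' Network representativeness: best SF against any station
#'
#' For every cell, the representativeness R by the whole network is the
#' highest SF the cell attains against any pseudo-station. Cells where no
#' station yields a defined SF stay undefined.
#'
#' @param sfMaps list of \linkS4class{SFMap}s sharing grid, pollutant and
#'   period.
#' @return A \linkS4class{RepresentativenessMap}.
#' @export
networkRepresentativeness <- function(sfMaps) {
  if (!length(sfMaps)) stop("need at least one SF map")
  stopifnot(all(vapply(sfMaps, is, TRUE, "SFMap")))
  g <- sfMaps[[1]]@grid
  for (m in sfMaps[-1])
    if (!sameGrid(g, m@grid)) stop("SF maps are on different grids")
  stk <- vapply(sfMaps, function(m) m@values,
                matrix(0, g@nRows, g@nCols))
  stk <- array(stk, dim = c(g@nRows, g@nCols, length(sfMaps)))
  r <- apply(stk, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  new("RepresentativenessMap", grid = g,
      pollutant = sfMaps[[1]]@pollutant, period = sfMaps[[1]]@period,
      values = r)
}

#' Area represented by a station or network
#'
#' Total area of the cells whose SF (or R) is strictly above the
#' well-represented cutoff, in square kilometres.
#'
#' @param map an \linkS4class{SFMap} or \linkS4class{RepresentativenessMap}.
#' @param cutoff well-represented cutoff (default 0.9, strict).
#' @return area in km^2.
#' @export
representedArea <- function(map, cutoff = 0.9) {
  stopifnot(cutoff > 0, cutoff < 1)
  n <- sum(mapValues(map) > cutoff, na.rm = TRUE)
  n * cellArea(gridSpec(map)) / 1e6
}

#' Population represented by a station or network
#'
#' Sum of person counts over cells whose SF (or R) is strictly above the
#' cutoff.
#'
#' @inheritParams representedArea
#' @param pop a \linkS4class{PopulationRaster} on the same grid.
#' @return persons.
#' @export
representedPopulation <- function(map, pop, cutoff = 0.9) {
  stopifnot(is(pop, "PopulationRaster"), cutoff > 0, cutoff < 1)
  if (!sameGrid(gridSpec(map), pop@grid))
    stop("population raster is on a different grid than the SF map")
  qual <- mapValues(map) > cutoff
  qual[is.na(qual)] <- FALSE
  sum(pop@counts[qual])
}

#' Population-health network representation index
#'
#' The PHNI of a domain is the population-weighted mean of the network
#' representativeness R over the domain's cells:
#' \deqn{PHNI_{p,d} = \sum_{i \in d} R_{p,i}\, pop_i \big/ \sum_{i \in d} pop_i}
#' Cells with undefined R are excluded from both sums (missing model
#' coverage does not count against the network).
#'
#' @param rMap a \linkS4class{RepresentativenessMap}.
#' @param pop a \linkS4class{PopulationRaster} on the same grid.
#' @param domain logical nRows-by-nCols membership matrix (default: whole
#'   grid).
#' @param domainName label for the output row.
#' @return one-row data.frame: \code{pollutant}, \code{domain},
#'   \code{period}, \code{phni}, \code{population} (persons entering the
#'   weighted mean).
#' @export
phni <- function(rMap, pop, domain = NULL, domainName = "all") {
  stopifnot(is(rMap, "RepresentativenessMap"), is(pop, "PopulationRaster"))
  if (!sameGrid(rMap@grid, pop@grid))
    stop("population raster is on a different grid than the R map")
  g <- rMap@grid
  if (is.null(domain)) domain <- matrix(TRUE, g@nRows, g@nCols)
  stopifnot(identical(dim(domain), c(g@nRows, g@nCols)))
  if (!any(domain)) stop("domain mask is empty")
  use <- domain & !is.na(rMap@values)
  wsum <- sum(pop@counts[use])
  if (wsum <= 0)
    stop("domain '", domainName, "' has zero population")
  val <- sum(rMap@values[use] * pop@counts[use]) / wsum
  data.frame(pollutant = rMap@pollutant, domain = domainName,
             period = rMap@period, phni = val, population = wsum,
             stringsAsFactors = FALSE)
}

#' Annual and seasonal period masks
#'
#' Splits an hourly time axis from a single calendar year into the five
#' analysis periods: annual, spring (March-May), summer (June-August),
#' autumn (September-November) and winter (December plus January-February
#' of the same year).
#'
#' @param time POSIXct hourly timestamps, all in one calendar year.
#' @return named list of logical masks (\code{annual}, \code{spring},
#'   \code{summer}, \code{autumn}, \code{winter}).
#' @export
seasonalPeriods <- function(time) {
  time <- as.POSIXct(time, tz = "UTC")
  yrs <- unique(format(time, "%Y"))
  if (length(yrs) > 1)
    stop("time axis spans multiple years (", paste(yrs, collapse = ", "),
         "); select a single year first")
  mon <- as.integer(format(time, "%m"))
  list(annual = rep(TRUE, length(time)),
       spring = mon %in% 3:5,
       summer = mon %in% 6:8,
       autumn = mon %in% 9:11,
       winter = mon %in% c(12, 1, 2))
}

#' Read district polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features with a
#' \code{name} property, in the grid's projected CRS.
#'
#' @param path GeoJSON file.
#' @return named list of polygon sets; each polygon set is a list of rings
#'   (two-column coordinate matrices, outer ring first; inner rings are
#'   holes).
#' @export
readDistricts <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  for (ft in gj$features) {
    nm <- ft$properties$name
    if (is.null(nm)) stop("district feature lacks a 'name' property")
    geom <- ft$geometry
    ringify <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    polys <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ringify)),
      MultiPolygon = lapply(geom$coordinates,
                            function(p) lapply(p, ringify)),
      stop("unsupported geometry type: ", geom$type))
    ## flatten multipolygon parts into one ring list per district
    out[[nm]] <- do.call(c, polys)
  }
  out
}

## logical membership matrix of grid-cell centroids in one ring list
## (even-odd rule: holes handled by in.out's crossing count)
districtMask <- function(rings, grid) {
  bnd <- do.call(rbind, lapply(rings, function(r)
    rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  cc <- cellCenters(grid)
  inside <- mgcv::in.out(bnd, cbind(cc$x, cc$y))
  mapFromCells(inside, grid)
}

#' District-level PHNI
#'
#' Assigns each grid cell to the district polygon containing its centroid
#' and computes one PHNI per district. Districts whose cells hold no
#' population are reported with \code{NA} rather than an error.
#'
#' @inheritParams phni
#' @param districts named list of polygon ring sets as returned by
#'   \code{\link{readDistricts}}, or a named list of logical membership
#'   matrices.
#' @return data.frame with one row per district (columns as \code{phni}).
#' @export
districtPHNI <- function(rMap, pop, districts) {
  stopifnot(length(districts) >= 1, !is.null(names(districts)))
  rows <- lapply(names(districts), function(nm) {
    d <- districts[[nm]]
    mask <- if (is.matrix(d) && is.logical(d)) d else
      districtMask(d, rMap@grid)
    if (!any(mask))
      return(data.frame(pollutant = rMap@pollutant, domain = nm,
                        period = rMap@period, phni = NA_real_,
                        population = 0, stringsAsFactors = FALSE))
    res <- tryCatch(phni(rMap, pop, mask, nm), error = function(e) NULL)
    if (is.null(res))
      data.frame(pollutant = rMap@pollutant, domain = nm,
                 period = rMap@period, phni = NA_real_, population = 0,
                 stringsAsFactors = FALSE)
    else res
  })
  do.call(rbind, rows)
}

#' Correlation between represented area and represented population
#'
#' Pearson correlation (with two-sided test) across stations between the
#' area and the population each station represents well. An exclusion list
#' supports sensitivity runs (e.g. dropping a background station with a
#' purpose unlike the rest of the network).
#'
#' @param summaries data.frame with columns \code{station_id},
#'   \code{area_km2}, \code{population} (one row per station, a single
#'   pollutant and period).
#' @param exclude character vector of station ids to drop.
#' @return list with \code{r}, \code{pValue}, \code{n}; \code{r} is NA when
#'   either vector has zero variance.
#' @export
areaPopulationCorrelation <- function(summaries, exclude = character()) {
  stopifnot(all(c("station_id", "area_km2", "population") %in%
                  names(summaries)))
  s <- summaries[!summaries$station_id %in% exclude, , drop = FALSE]
  if (nrow(s) < 3) stop("need at least 3 stations for a correlation")
  a <- s$area_km2; p <- s$population
  if (sd(a) == 0 || sd(p) == 0)
    return(list(r = NA_real_, pValue = NA_real_, n = nrow(s)))
  ct <- cor.test(a, p, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), pValue = ct$p.value, n = nrow(s))
}
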