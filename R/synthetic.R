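## synthetic_data module: seeded scenario generator producing concentration
## fields, stations, population and districts with the statistical structure
## the method is designed to probe: a temporally autocorrelated regional
## background shared by all cells, traffic-like exponential source plumes,
## an NO2/O3 pair anticorrelated under a spatially conserved total oxidant
## (Ox) field, PM intermediate between regional and local, and a heavily
## clustered population.

#' Default per-pollutant background levels
#'
#' Annual and seasonal domain-mean levels used by the scenario generator
#' (PM in micrograms per cubic metre, gases in ppb), patterned on the
#' monsoon-driven seasonality of a subtropical coastal city: PM and NO2
#' peak in autumn/winter under continental transport, O3 peaks in autumn.
#'
#' @return data.frame with columns pollutant, annual, spring, summer,
#'   autumn, winter.
#' @export
defaultBackgroundLevels <- function() {
  data.frame(
    pollutant = c("PM10", "PM2.5", "NO2", "O3"),
    annual = c(32.2, 19.2, 20.5, 30.4),
    spring = c(26.7, 16.5, 19.1, 29.7),
    summer = c(20.9, 12.1, 16.8, 21.1),
    autumn = c(40.7, 23.9, 21.0, 44.8),
    winter = c(40.6, 24.4, 25.0, 26.0),
    stringsAsFactors = FALSE)
}

#' Scenario configuration
#'
#' Bundles and validates every knob of the synthetic scenario. Defaults
#' describe a 30 x 30 grid of 45 x 48 m cells over 720 hours with two
#' traffic-like NO2 line sources (peak 20 ppb, 200 m e-folding decay,
#' diurnal modulation), an Ox-conserving NO2/O3 pair, PM that is 65 percent
#' (PM10) / 40 percent (PM2.5) regional, and a clustered population.
#'
#' @param seed integer RNG seed; required, the scenario is fully
#'   deterministic given it.
#' @param grid analysis \linkS4class{GridSpec}.
#' @param nHours number of hourly steps.
#' @param startTime first timestamp (UTC).
#' @param background data.frame of per-pollutant annual/seasonal mean
#'   levels, see \code{\link{defaultBackgroundLevels}}; gases in ppb, PM in
#'   ug/m3.
#' @param ar1Phi temporal AR(1) coefficient of the regional background, in
#'   [0, 1).
#' @param noiseSdFrac stationary sd of the background as a fraction of its
#'   mean level.
#' @param spatialNoiseSdFrac sd of iid cell-hour noise as a fraction of the
#'   mean level (default 0: the regional background is spatially
#'   homogeneous; heterogeneity enters through sources).
#' @param sources list of local sources; each a list with \code{pollutant},
#'   \code{type} ("line" or "point"), coordinates (\code{x}, \code{y} for
#'   points; \code{x0}, \code{y0}, \code{x1}, \code{y1} for lines),
#'   \code{strength} (peak concentration increment at the source, in the
#'   pollutant's unit) and \code{decay} (e-folding length in metres).
#' @param oxMode \code{"ox_conserved"} (NO2 + O3 spatially constant per
#'   hour before clipping at 0) or \code{"independent"}.
#' @param pmRegionalFraction named fractions in [0, 1] of PM10/PM2.5 mass
#'   that is regional (spatially homogeneous); the remainder follows the
#'   local source plume geometry.
#' @param pmScale multiplier applied to both PM background levels (used to
#'   set PM's share of the combined risk).
#' @param population list: \code{nClusters}, \code{clusterSd} (m),
#'   \code{total} persons.
#' @param stations data.frame (id, type, x, y) or NULL to place
#'   \code{stationCounts} at random.
#' @param stationCounts named integer vector by station type, used when
#'   \code{stations} is NULL.
#' @return validated config list of class \code{"ScenarioConfig"}.
#' @export
ScenarioConfig <- function(seed,
                           grid = GridSpec(820000, 815000, 45, 48,
                                           nCols = 30, nRows = 30),
                           nHours = 720,
                           startTime = "2019-01-01 00:00:00",
                           background = defaultBackgroundLevels(),
                           ar1Phi = 0.9,
                           noiseSdFrac = 0.15,
                           spatialNoiseSdFrac = 0,
                           sources = defaultSources(grid),
                           oxMode = c("ox_conserved", "independent"),
                           pmRegionalFraction = c(PM10 = 0.65,
                                                  `PM2.5` = 0.40),
                           pmScale = 1,
                           population = list(nClusters = 5,
                                             clusterSd = 150,
                                             total = 1e5),
                           stations = NULL,
                           stationCounts = c(general = 1, roadside = 1,
                                             background = 1)) {
  if (missing(seed)) stop("an explicit seed is required")
  oxMode <- match.arg(oxMode)
  if (!is.finite(ar1Phi) || ar1Phi < 0 || ar1Phi >= 1)
    stop("invalid ar1Phi: must lie in [0, 1)")
  if (noiseSdFrac < 0 || spatialNoiseSdFrac < 0)
    stop("invalid noise sd fraction: must be nonnegative")
  if (any(pmRegionalFraction < 0 | pmRegionalFraction > 1))
    stop("invalid pmRegionalFraction: must lie in [0, 1]")
  if (!is.null(population$total) && population$total <= 0)
    stop("invalid population total: must be positive")
  if (nHours < 1) stop("invalid nHours")
  for (s in sources) {
    if (!s$pollutant %in% POLLUTANTS)
      stop("invalid source pollutant: ", s$pollutant)
    if (!is.finite(s$decay) || s$decay <= 0)
      stop("invalid source decay length: must be positive")
    if (!is.finite(s$strength) || s$strength < 0)
      stop("invalid source strength")
  }
  structure(list(seed = as.integer(seed), grid = grid, nHours = nHours,
                 startTime = startTime, background = background,
                 ar1Phi = ar1Phi, noiseSdFrac = noiseSdFrac,
                 spatialNoiseSdFrac = spatialNoiseSdFrac,
                 sources = sources, oxMode = oxMode,
                 pmRegionalFraction = pmRegionalFraction,
                 pmScale = pmScale, population = population,
                 stations = stations, stationCounts = stationCounts),
            class = "ScenarioConfig")
}

#' Default local sources: two parallel traffic-like NO2 line sources
#'
#' Peak 20 ppb at the road, 200 m e-folding decay, crossing the domain
#' horizontally at 1/3 and 2/3 of its height.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @return list of source descriptors.
#' @export
defaultSources <- function(grid) {
  W <- grid@nCols * grid@dx
  H <- grid@nRows * grid@dy
  mk <- function(fy) list(pollutant = "NO2", type = "line",
                          x0 = grid@originX, y0 = grid@originY + fy * H,
                          x1 = grid@originX + W, y1 = grid@originY + fy * H,
                          strength = 20, decay = 200)
  list(mk(1 / 3), mk(2 / 3))
}

## distance from points (x, y) to one source
sourceDistance <- function(src, x, y) {
  if (src$type == "point")
    return(sqrt((x - src$x)^2 + (y - src$y)^2))
  vx <- src$x1 - src$x0; vy <- src$y1 - src$y0
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) rep(0, length(x)) else
    pmin(pmax(((x - src$x0) * vx + (y - src$y0) * vy) / L2, 0), 1)
  sqrt((x - (src$x0 + t * vx))^2 + (y - (src$y0 + t * vy))^2)
}

## AR(1) series around a time-varying mean mu_t with stationary sd
## sdFrac * mean(mu)
ar1Series <- function(mu, phi, sdFrac) {
  n <- length(mu)
  statSd <- sdFrac * mean(mu)
  innovSd <- statSd * sqrt(1 - phi^2)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, statSd)
  if (n > 1)
    for (t in 2:n) e[t] <- phi * e[t - 1] + rnorm(1, 0, innovSd)
  pmax(mu + e, 0)
}

## diurnal traffic modulation in [0.3, 1]
diurnalProfile <- function(hourOfDay) {
  0.3 + 0.7 * (1 + sin(2 * pi * (hourOfDay - 6) / 24)) / 2
}

seasonOfMonth <- function(mon) {
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[mon]
}

#' Generate a complete synthetic scenario
#'
#' Builds hourly concentration fields for the four pollutants, a located
#' station table, a clustered population raster and quadrant district
#' masks, deterministically from the config's seed. In
#' \code{"ox_conserved"} mode an hourly total-oxidant level is generated
#' and shared by every cell; NO2 plumes then titrate O3 locally
#' (\eqn{O_3 = Ox - NO_2}, clipped at 0), so NO2 + O3 is spatially constant
#' per hour wherever clipping does not occur.
#'
#' @param config a \code{\link{ScenarioConfig}}.
#' @return list with \code{fields} (named \linkS4class{ConcentrationField}
#'   list; gases in ppb, PM in ug/m3), \code{stations} (located table),
#'   \code{population} (\linkS4class{PopulationRaster}), \code{districts}
#'   (named list of logical masks), \code{time} and \code{config}.
#' @export
generateScenario <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)

  g <- config$grid
  nc <- nCells(g)
  tm <- as.POSIXct(config$startTime, tz = "UTC") +
    3600 * (seq_len(config$nHours) - 1)
  mon <- as.integer(format(tm, "%m"))
  seas <- seasonOfMonth(mon)
  hod <- as.integer(format(tm, "%H"))
  mod <- diurnalProfile(hod)
  bg <- config$background
  meanOf <- function(p, s) bg[bg$pollutant == p, s]
  muSeries <- function(p, scale = 1)
    scale * vapply(seas, function(s) meanOf(p, s), numeric(1))

  cc <- cellCenters(g)
  plumeShape <- function(pol) {   # nc-vector of summed source kernels
    shape <- numeric(nc)
    for (s in config$sources)
      if (s$pollutant == pol)
        shape <- shape + s$strength *
          exp(-sourceDistance(s, cc$x, cc$y) / s$decay)
    shape
  }
  spatNoise <- function(meanLevel) {
    if (config$spatialNoiseSdFrac == 0) return(0)
    matrix(rnorm(nc * config$nHours, 0,
                 config$spatialNoiseSdFrac * meanLevel),
           nc, config$nHours)
  }

  fields <- list()

  ## gases
  no2Shape <- plumeShape("NO2")
  plumeNO2 <- outer(no2Shape, mod)       # nc x nHours
  if (config$oxMode == "ox_conserved") {
    muNO2 <- muSeries("NO2"); muO3 <- muSeries("O3")
    oxT <- ar1Series(muNO2 + muO3, config$ar1Phi, config$noiseSdFrac)
    rT <- muNO2 / (muNO2 + muO3)          # seasonal NO2 share of Ox
    no2bg <- oxT * rT
    no2 <- matrix(no2bg, nc, config$nHours, byrow = TRUE) + plumeNO2 +
      spatNoise(mean(muNO2))
    no2 <- pmax(no2, 0)
    o3 <- pmax(matrix(oxT, nc, config$nHours, byrow = TRUE) - no2, 0)
  } else {
    no2bg <- ar1Series(muSeries("NO2"), config$ar1Phi, config$noiseSdFrac)
    no2 <- pmax(matrix(no2bg, nc, config$nHours, byrow = TRUE) + plumeNO2 +
                  spatNoise(meanOf("NO2", "annual")), 0)
    o3bg <- ar1Series(muSeries("O3"), config$ar1Phi, config$noiseSdFrac)
    o3 <- pmax(matrix(o3bg, nc, config$nHours, byrow = TRUE) +
                 outer(plumeShape("O3"), mod) +
                 spatNoise(meanOf("O3", "annual")), 0)
  }
  fields$NO2 <- ConcentrationField(no2, g, tm, "NO2", "ppb")
  fields$O3 <- ConcentrationField(o3, g, tm, "O3", "ppb")

  ## particulates: regional fraction homogeneous, remainder follows the
  ## local plume geometry of all sources
  allShape <- numeric(nc)
  for (s in config$sources)
    allShape <- allShape + exp(-sourceDistance(s, cc$x, cc$y) / s$decay)
  shapeNorm <- if (any(allShape > 0)) allShape / mean(allShape) else
    rep(1, nc)
  for (p in c("PM10", "PM2.5")) {
    frac <- config$pmRegionalFraction[[p]]
    bgT <- ar1Series(muSeries(p, config$pmScale), config$ar1Phi,
                     config$noiseSdFrac)
    meanLvl <- config$pmScale * meanOf(p, "annual")
    localMat <- meanLvl * outer(shapeNorm, mod / mean(mod))
    pm <- frac * matrix(bgT, nc, config$nHours, byrow = TRUE) +
      (1 - frac) * localMat + spatNoise(meanLvl)
    fields[[p]] <- ConcentrationField(pmax(pm, 0), g, tm, p, "ug/m3")
  }

  ## stations
  W <- g@nCols * g@dx; H <- g@nRows * g@dy
  if (is.null(config$stations)) {
    cnt <- config$stationCounts
    rows <- list()
    k <- 0
    anchor <- list(
      general = function() c(g@originX + runif(1, 0.35, 0.65) * W,
                             g@originY + runif(1, 0.4, 0.6) * H),
      roadside = function() {
        lines <- Filter(function(s) s$type == "line", config$sources)
        if (length(lines)) {
          s <- lines[[1 + (k %% length(lines))]]
          t <- runif(1, 0.2, 0.8)
          c(s$x0 + t * (s$x1 - s$x0), s$y0 + t * (s$y1 - s$y0))
        } else c(g@originX + runif(1) * W, g@originY + runif(1) * H)
      },
      background = function() c(g@originX + runif(1, 0.85, 0.98) * W,
                                g@originY + runif(1, 0.85, 0.98) * H))
    for (type in names(cnt)) for (i in seq_len(cnt[[type]])) {
      k <- k + 1
      xy <- anchor[[type]]()
      rows[[k]] <- data.frame(
        id = sprintf("%s%d", toupper(substr(type, 1, 2)), i),
        type = type, x = xy[1], y = xy[2],
        inlet_height_m = switch(type, general = 20, roadside = 4,
                                background = 11),
        stringsAsFactors = FALSE)
    }
    stations <- do.call(rbind, rows)
  } else stations <- config$stations
  stations <- locatePseudoStations(stations, g)

  ## population: mixture of Gaussian clusters, strictly positive
  pc <- config$population
  ctrX <- g@originX + runif(pc$nClusters, 0.1, 0.9) * W
  ctrY <- g@originY + runif(pc$nClusters, 0.1, 0.9) * H
  wts <- runif(pc$nClusters, 0.5, 1.5)
  dens <- numeric(nc)
  for (k in seq_len(pc$nClusters))
    dens <- dens + wts[k] *
      exp(-((cc$x - ctrX[k])^2 + (cc$y - ctrY[k])^2) / (2 * pc$clusterSd^2))
  dens <- dens + 1e-6 * max(dens)
  popCells <- dens / sum(dens) * pc$total
  population <- PopulationRaster(mapFromCells(popCells, g), g)

  ## quadrant districts
  midR <- g@nRows %/% 2; midC <- g@nCols %/% 2
  rr <- row(matrix(0, g@nRows, g@nCols)); cm <- col(matrix(0, g@nRows, g@nCols))
  districts <- list(SW = rr <= midR & cm <= midC,
                    SE = rr <= midR & cm > midC,
                    NW = rr > midR & cm <= midC,
                    NE = rr > midR & cm > midC)

  list(fields = fields, stations = stations, population = population,
       districts = districts, time = tm, config = config)
}

#' Quadrant district polygons
#'
#' The four quadrants of the grid as closed GeoJSON-style rectangles, for
#' exercising the polygon-based district assignment on synthetic
#' scenarios.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @return named list of polygon ring sets (see \code{\link{readDistricts}}).
#' @export
quadrantDistrictPolygons <- function(grid) {
  midX <- grid@originX + (grid@nCols %/% 2) * grid@dx
  midY <- grid@originY + (grid@nRows %/% 2) * grid@dy
  x0 <- grid@originX; y0 <- grid@originY
  x1 <- grid@originX + grid@nCols * grid@dx
  y1 <- grid@originY + grid@nRows * grid@dy
  rect <- function(xa, ya, xb, yb)
    list(rbind(c(xa, ya), c(xb, ya), c(xb, yb), c(xa, yb), c(xa, ya)))
  list(SW = rect(x0, y0, midX, midY), SE = rect(midX, y0, x1, midY),
       NW = rect(x0, midY, midX, y1), NE = rect(midX, midY, x1, y1))
}
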