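## End-to-end evaluation: concentrations -> %AR -> SF per station ->
## network R -> PHNI (global, seasonal, district).

#' Excess-risk fields for all pollutants plus the combined risk
#'
#' Converts gaseous fields from ppb where needed, applies the
#' concentration-response transform to each pollutant, and forms the
#' combined risk field.
#'
#' @param concFields named list of \linkS4class{ConcentrationField}s with
#'   entries \code{PM10}, \code{PM2.5}, \code{NO2}, \code{O3}.
#' @param coeffs risk slopes per ug/m3 (\code{\link{riskCoefficients}}).
#' @param temperatureC,pressureHPa gas conversion conditions.
#' @return named list of five \linkS4class{ARField}s (the four pollutants
#'   and \code{total}).
#' @export
computeARFields <- function(concFields, coeffs = riskCoefficients(),
                            temperatureC = 25, pressureHPa = 1013.25) {
  stopifnot(all(POLLUTANTS %in% names(concFields)))
  ar <- lapply(concFields[POLLUTANTS], function(f)
    computeAR(convertUnits(f, temperatureC, pressureHPa), coeffs))
  ar$total <- computeARTotal(ar[["PM2.5"]], ar[["PM10"]], ar[["NO2"]],
                             ar[["O3"]])
  ar
}

#' Evaluate network representativeness for one excess-risk field
#'
#' For one quantity (a pollutant or the combined risk) and a set of
#' periods: computes the SF map of every station, the per-station
#' represented area and population, the network representativeness map and
#' the PHNI of the whole domain and (optionally) of each district.
#'
#' @param arField an \linkS4class{ARField}.
#' @param stations located station table
#'   (\code{\link{locatePseudoStations}}).
#' @param pop a \linkS4class{PopulationRaster} on the field's grid.
#' @param districts optional named list of polygon ring sets or logical
#'   membership matrices.
#' @param periods subset of annual/spring/summer/autumn/winter; each is
#'   evaluated independently, recomputing SF on the period's hours.
#' @param threshold SF similarity threshold (relative difference).
#' @param cutoff well-represented cutoff for area/population tallies.
#' @param minCoverage minimum joint coverage for a defined SF.
#' @param reference relative-difference denominator, see
#'   \code{\link{similarityFrequency}}.
#' @return list: \code{sfMaps} (list period -> station id ->
#'   \linkS4class{SFMap}), \code{rMaps} (period ->
#'   \linkS4class{RepresentativenessMap}), \code{stationSummary}
#'   (data.frame station_id, pollutant, period, area_km2, population),
#'   \code{phniTable} (data.frame, whole domain plus districts).
#' @export
evaluateNetwork <- function(arField, stations, pop, districts = NULL,
                            periods = "annual", threshold = 0.2,
                            cutoff = 0.9, minCoverage = 0.75,
                            reference = "station") {
  stopifnot(is(arField, "ARField"), nrow(stations) >= 1)
  periods <- match.arg(periods, PERIODS, several.ok = TRUE)
  masks <- seasonalPeriods(fieldTime(arField))
  sfMaps <- list(); rMaps <- list()
  sumRows <- list(); phniRows <- list()
  for (per in periods) {
    pm <- masks[[per]]
    if (!any(pm)) stop("period '", per, "' selects no hours")
    maps <- lapply(seq_len(nrow(stations)), function(s)
      sfMap(arField, stations[s, , drop = FALSE], periodMask = pm,
            period = per, threshold = threshold,
            minCoverage = minCoverage, reference = reference))
    names(maps) <- stations$id
    sfMaps[[per]] <- maps
    for (sid in names(maps)) {
      m <- maps[[sid]]
      sumRows[[paste(per, sid)]] <- data.frame(
        station_id = sid, pollutant = arField@pollutant, period = per,
        area_km2 = representedArea(m, cutoff),
        population = representedPopulation(m, pop, cutoff),
        stringsAsFactors = FALSE)
    }
    rMap <- networkRepresentativeness(maps)
    rMaps[[per]] <- rMap
    phniRows[[per]] <- phni(rMap, pop, domainName = "all")
    if (!is.null(districts))
      phniRows[[paste0(per, ".districts")]] <-
        districtPHNI(rMap, pop, districts)
  }
  list(sfMaps = sfMaps, rMaps = rMaps,
       stationSummary = do.call(rbind, c(sumRows,
                                         list(make.row.names = FALSE))),
       phniTable = do.call(rbind, c(phniRows,
                                    list(make.row.names = FALSE))))
}

#' Evaluate a whole scenario across pollutants
#'
#' Convenience driver: risk transform plus
#' \code{\link{evaluateNetwork}} for each pollutant and the combined risk.
#'
#' @param scenario output of \code{\link{generateScenario}}, or a list with
#'   the same \code{fields}/\code{stations}/\code{population}/
#'   \code{districts} entries built from ingested data.
#' @param quantities which quantities to evaluate (default: all four
#'   pollutants and \code{"total"}).
#' @inheritParams evaluateNetwork
#' @inheritParams computeARFields
#' @param useDistricts evaluate district PHNI with the scenario's district
#'   masks.
#' @return named list (one entry per quantity) of
#'   \code{\link{evaluateNetwork}} results.
#' @export
evaluateScenario <- function(scenario, quantities = QUANTITIES,
                             periods = "annual",
                             coeffs = riskCoefficients(), threshold = 0.2,
                             cutoff = 0.9, minCoverage = 0.75,
                             reference = "station", useDistricts = TRUE,
                             temperatureC = 25, pressureHPa = 1013.25) {
  quantities <- match.arg(quantities, QUANTITIES, several.ok = TRUE)
  ar <- computeARFields(scenario$fields, coeffs, temperatureC, pressureHPa)
  districts <- if (useDistricts) scenario$districts else NULL
  out <- lapply(ar[quantities], evaluateNetwork,
                stations = scenario$stations, pop = scenario$population,
                districts = districts, periods = periods,
                threshold = threshold, cutoff = cutoff,
                minCoverage = minCoverage, reference = reference)
  out
}
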