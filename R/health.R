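## health_risk module: unit conversion and the exponential
## concentration-response transform to excess hospital-admission risk.

MOLAR_MASS <- c(NO2 = 46.0055, O3 = 48.00)  # g/mol

#' Default excess-risk slopes
#'
#' Short-term hospital-admission risk slopes per microgram per cubic metre,
#' for all age groups, from the Hong Kong air quality health index studies
#' (Wong and colleagues). Under the exponential concentration-response
#' \eqn{\%AR = (e^{\beta C} - 1)\times 100} they give 0.022\%, 0.028\%,
#' 0.045\% and 0.051\% added risk per 1 \eqn{\mu g/m^3} of PM2.5, PM10, NO2
#' and O3 respectively.
#'
#' @param PM2.5,PM10,NO2,O3 slopes per microgram per cubic metre.
#' @param note free-text provenance note carried along with the values.
#' @return named numeric vector with a \code{"note"} attribute.
#' @export
riskCoefficients <- function(`PM2.5` = 2.180567e-4, PM10 = 2.821751e-4,
                             NO2 = 4.462559e-4, O3 = 5.116328e-4,
                             note = "HK AQHI all-age hospital admissions") {
  beta <- c("PM2.5" = `PM2.5`, PM10 = PM10, NO2 = NO2, O3 = O3)
  if (any(!is.finite(beta)) || any(beta <= 0))
    stop("all risk coefficients must be positive")
  attr(beta, "note") <- note
  beta
}

#' Molar volume of an ideal gas
#'
#' Anchored to the conventional 24.45 L/mol at 25 degrees C and
#' 1013.25 hPa used in air-quality reporting, and scaled by the ideal gas
#' law for other conditions.
#'
#' @param temperatureC air temperature in degrees Celsius.
#' @param pressureHPa pressure in hectopascal.
#' @return litres per mole.
#' @export
molarVolume <- function(temperatureC = 25, pressureHPa = 1013.25) {
  24.45 * ((temperatureC + 273.15) / 298.15) * (1013.25 / pressureHPa)
}

#' Convert a gaseous concentration field from ppb to micrograms per cubic
#' metre
#'
#' \eqn{\mu g/m^3 = ppb \times M / V_m} with the pollutant's molar mass M and
#' the molar volume at the given conditions. Fields already in
#' \eqn{\mu g/m^3} pass through unchanged; particulate fields are never in
#' ppb.
#'
#' @param field a \linkS4class{ConcentrationField}.
#' @param temperatureC,pressureHPa conversion conditions (defaults 25 C,
#'   1013.25 hPa, the common reporting convention).
#' @return A \linkS4class{ConcentrationField} in \code{"ug/m3"}.
#' @export
convertUnits <- function(field, temperatureC = 25, pressureHPa = 1013.25) {
  stopifnot(is(field, "ConcentrationField"))
  if (field@unit == "ug/m3") return(field)
  p <- field@pollutant
  if (!p %in% names(MOLAR_MASS))
    stop("ppb unit is only meaningful for gaseous pollutants, not ", p)
  f <- MOLAR_MASS[[p]] / molarVolume(temperatureC, pressureHPa)
  ConcentrationField(fieldValues(field) * f, field@grid, fieldTime(field),
                     p, unit = "ug/m3")
}

#' Excess hospital-admission risk from a concentration field
#'
#' Applies the additive-risk transform
#' \eqn{\%AR_{p,j,t} = (e^{\beta_p C_{p,j,t}} - 1) \times 100} cell-wise and
#' hour-wise. Missing concentrations stay missing.
#'
#' @param field a \linkS4class{ConcentrationField} in \code{"ug/m3"}.
#' @param coeffs named slopes per \eqn{\mu g/m^3}, see
#'   \code{\link{riskCoefficients}}.
#' @return An \linkS4class{ARField} in percent.
#' @export
computeAR <- function(field, coeffs = riskCoefficients()) {
  stopifnot(is(field, "ConcentrationField"))
  if (field@unit != "ug/m3")
    stop("concentrations must be in ug/m3; run convertUnits() first")
  p <- field@pollutant
  if (!p %in% names(coeffs) || is.na(coeffs[[p]]))
    stop("no risk coefficient available for pollutant ", p)
  ar <- (exp(coeffs[[p]] * fieldValues(field)) - 1) * 100
  ARField(ar, field@grid, fieldTime(field), p)
}

#' Combined excess risk from the four pollutants
#'
#' At each cell and hour the combined short-term risk adds the NO2 and O3
#' risks to the larger of the PM2.5 and PM10 risks (the two PM size
#' fractions overlap, so only the higher one counts). The result is missing
#' wherever any input is missing.
#'
#' @param arPM25,arPM10,arNO2,arO3 \linkS4class{ARField}s on the same grid
#'   and time axis.
#' @return An \linkS4class{ARField} with \code{pollutant = "total"}.
#' @export
computeARTotal <- function(arPM25, arPM10, arNO2, arO3) {
  flds <- list(arPM25, arPM10, arNO2, arO3)
  stopifnot(all(vapply(flds, is, TRUE, "ARField")))
  g <- arPM25@grid
  tm <- fieldTime(arPM25)
  for (f in flds[-1]) {
    if (!sameGrid(g, f@grid)) stop("AR fields are on different grids")
    if (length(fieldTime(f)) != length(tm) || !all(fieldTime(f) == tm))
      stop("AR fields have different time axes")
  }
  v25 <- fieldValues(arPM25); v10 <- fieldValues(arPM10)
  vNO2 <- fieldValues(arNO2); vO3 <- fieldValues(arO3)
  total <- vNO2 + vO3 + pmax(v25, v10)
  total[is.na(v25) | is.na(v10) | is.na(vNO2) | is.na(vO3)] <- NA_real_
  ARField(total, g, tm, "total")
}
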