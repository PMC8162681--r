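## similarity module: similarity frequency between %AR series and banding.

SF_BANDS <- c("low", "medium", "medium_high", "high")

#' Similarity frequency between two hourly series
#'
#' The similarity frequency (SF) is the fraction of timesteps at which a
#' cell's value differs from the reference (station) value by no more than a
#' relative threshold: a timestep counts as similar iff
#' \eqn{|a_t - b_t| / b_t \le} \code{threshold}, with \eqn{b} the station
#' series. Timesteps missing in either series are excluded from both
#' numerator and denominator; if fewer than \code{minCoverage} of the
#' timesteps remain, SF is undefined (\code{NA}). Where the reference is
#' (numerically) zero the relative criterion degenerates, and a timestep is
#' similar iff the two values agree within \code{eps}.
#'
#' @param cellSeries,stationSeries numeric vectors on a shared time axis.
#' @param threshold maximum relative difference counted as similar
#'   (default 0.2, i.e. 20 percent).
#' @param minCoverage minimum fraction of the series length that must be
#'   jointly present for SF to be defined (default 0.75).
#' @param reference \code{"station"} (default) divides by the station value;
#'   \code{"max"} divides by the elementwise maximum of the pair, a
#'   symmetric alternative.
#' @param eps floor below which a reference value is treated as zero.
#' @return list with \code{sf} (in [0,1] or NA) and \code{nValid}.
#' @export
similarityFrequency <- function(cellSeries, stationSeries, threshold = 0.2,
                                minCoverage = 0.75,
                                reference = c("station", "max"),
                                eps = 1e-9) {
  reference <- match.arg(reference)
  if (length(cellSeries) != length(stationSeries))
    stop("series lengths differ: time axes must match")
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be a positive number")
  ok <- !is.na(cellSeries) & !is.na(stationSeries)
  n <- sum(ok)
  if (n < minCoverage * length(cellSeries))
    return(list(sf = NA_real_, nValid = n))
  a <- cellSeries[ok]
  b <- stationSeries[ok]
  ref <- if (reference == "station") b else pmax(a, b)
  deg <- abs(ref) < eps
  similar <- logical(n)
  similar[!deg] <- abs(a[!deg] - b[!deg]) / ref[!deg] <= threshold
  similar[deg] <- abs(a[deg] - b[deg]) < eps
  list(sf = sum(similar) / n, nValid = n)
}

#' Similarity-frequency map of one pseudo-station
#'
#' Computes the SF of every grid cell's \%AR series against the
#' pseudo-station's series over the hours selected by \code{periodMask}.
#' The station's own cell is set to SF = 1 (it is its own perfect
#' reference).
#'
#' @param arField an \linkS4class{ARField} (single pollutant or total).
#' @param station one-row station table as returned by
#'   \code{\link{locatePseudoStations}} (columns \code{id}, \code{cell}).
#' @param periodMask logical vector over the field's time axis selecting the
#'   period's hours (default: all hours).
#' @param period label stored on the result.
#' @inheritParams similarityFrequency
#' @return An \linkS4class{SFMap}.
#' @export
sfMap <- function(arField, station, periodMask = NULL, period = "annual",
                  threshold = 0.2, minCoverage = 0.75,
                  reference = c("station", "max"), eps = 1e-9) {
  reference <- match.arg(reference)
  stopifnot(is(arField, "ARField"))
  if (is.data.frame(station)) {
    stopifnot(nrow(station) == 1L)
    sid <- as.character(station$id)
    scell <- station$cell
  } else stop("station must be a one-row data.frame with id and cell")
  v <- fieldValues(arField)
  if (is.null(periodMask)) periodMask <- rep(TRUE, ncol(v))
  stopifnot(length(periodMask) == ncol(v))
  v <- v[, periodMask, drop = FALSE]
  b <- v[scell, ]
  if (all(is.na(b)))
    stop("pseudo-station cell is fully missing for station ", sid)

  nT <- ncol(v)
  bOk <- !is.na(b)
  aOk <- !is.na(v)
  okMat <- aOk & rep(bOk, each = nrow(v))
  nValid <- rowSums(okMat)

  bm <- matrix(b, nrow = nrow(v), ncol = nT, byrow = TRUE)
  refM <- if (reference == "station") bm else pmax(v, bm)
  deg <- abs(refM) < eps
  deg[is.na(deg)] <- FALSE
  simMat <- (abs(v - bm) / refM <= threshold) & !deg
  simMat[deg] <- (abs(v - bm) < eps)[deg]
  simMat[!okMat] <- FALSE
  sf <- rowSums(simMat) / nValid
  sf[nValid < minCoverage * nT] <- NA_real_
  sf[scell] <- 1
  new("SFMap", grid = arField@grid, stationId = sid,
      pollutant = arField@pollutant, period = period,
      values = mapFromCells(sf, arField@grid),
      nValid = mapFromCells(as.integer(nValid), arField@grid))
}

#' Classify SF values into representation bands
#'
#' Bands partition [0, 1]: \code{low} [0, 0.5), \code{medium} [0.5, 0.7),
#' \code{medium_high} [0.7, 0.9], \code{high} (0.9, 1]. "High"
#' (well-represented) requires SF strictly above 0.9.
#'
#' @param sf numeric vector of SF values in [0, 1] (NA passes through).
#' @return factor with levels low/medium/medium_high/high.
#' @export
classifyBand <- function(sf) {
  if (any(sf < 0 | sf > 1, na.rm = TRUE))
    stop("SF values must lie in [0, 1]")
  out <- character(length(sf))
  out[sf < 0.5] <- "low"
  out[sf >= 0.5 & sf < 0.7] <- "medium"
  out[sf >= 0.7 & sf <= 0.9] <- "medium_high"
  out[sf > 0.9] <- "high"
  out[is.na(sf)] <- NA_character_
  factor(out, levels = SF_BANDS)
}
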