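## verification module: model-vs-observation agreement statistics.

pairSeries <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed series must share a time axis")
  ok <- !is.na(predicted) & !is.na(observed)
  list(p = predicted[ok], o = observed[ok], n = sum(ok))
}

#' Willmott index of agreement
#'
#' \deqn{IOA = 1 - \frac{\sum (P_i - O_i)^2}{\sum (|P_i - \bar O| + |O_i - \bar O|)^2}}
#' Bounded above by 1, with 1 iff the modelled series equals the
#' observations. Undefined (NA, with a warning) when the observations are
#' constant. \code{denominator = "printed"} replaces \eqn{|P_i - \bar O|}
#' with \eqn{|P_i + \bar O|}, an audit variant of a formula occasionally
#' seen in print; it is not bounded the way the standard index is and is
#' not the default.
#'
#' @param predicted,observed hourly series on a shared time axis (pairs
#'   with a missing value in either are dropped).
#' @param denominator \code{"anomaly"} (standard, default) or
#'   \code{"printed"}.
#' @return scalar IOA.
#' @export
ioa <- function(predicted, observed, denominator = c("anomaly", "printed")) {
  denominator <- match.arg(denominator)
  s <- pairSeries(predicted, observed)
  if (s$n < 2) stop("need at least 2 valid pairs")
  if (all(s$o == s$o[1])) {
    warning("observed series is constant; IOA undefined")
    return(NA_real_)
  }
  obar <- mean(s$o)
  num <- sum((s$p - s$o)^2)
  pterm <- if (denominator == "anomaly") abs(s$p - obar) else abs(s$p + obar)
  den <- sum((pterm + abs(s$o - obar))^2)
  if (den == 0) {
    warning("observed series is constant; IOA undefined")
    return(NA_real_)
  }
  1 - num / den
}

#' Root mean square error
#'
#' @inheritParams ioa
#' @return scalar RMSE (same units as the series).
#' @export
rmse <- function(predicted, observed) {
  s <- pairSeries(predicted, observed)
  if (s$n < 1) stop("need at least 1 valid pair")
  sqrt(mean((s$p - s$o)^2))
}

#' Verification table for paired model/observation series
#'
#' @param pairs data.frame with columns \code{station_id}, \code{pollutant},
#'   \code{predicted}, \code{observed} (long format, one row per hour).
#' @param denominator passed to \code{\link{ioa}}.
#' @return data.frame with one row per (station, pollutant): \code{n},
#'   \code{rmse}, \code{ioa}.
#' @export
verificationTable <- function(pairs, denominator = "anomaly") {
  stopifnot(all(c("station_id", "pollutant", "predicted", "observed") %in%
                  names(pairs)))
  keys <- unique(pairs[c("station_id", "pollutant")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- pairs[pairs$station_id == keys$station_id[i] &
                   pairs$pollutant == keys$pollutant[i], ]
    ok <- !is.na(sub$predicted) & !is.na(sub$observed)
    data.frame(station_id = keys$station_id[i],
               pollutant = keys$pollutant[i], n = sum(ok),
               rmse = rmse(sub$predicted, sub$observed),
               ioa = ioa(sub$predicted, sub$observed,
                         denominator = denominator),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
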