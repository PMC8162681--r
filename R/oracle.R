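## Independent brute-force reference implementation. Recomputes the whole
## chain -- unit conversion, %AR, similarity frequency, network maximum and
## population-weighted index -- with plain nested loops and no shared code
## with the pipeline, for use as an equivalence check on small instances.

#' Brute-force reference computation of SF, R and PHNI
#'
#' Recomputes, with scalar loops only, the annual similarity-frequency map
#' of every station, the per-cell network representativeness and the
#' domain PHNI for each pollutant and the combined risk, from a generated
#' scenario. Intended solely as an independent cross-check of the
#' vectorized pipeline on small instances (at most 50 x 50 cells and 2000
#' hours).
#'
#' @param scenario output of \code{\link{generateScenario}}.
#' @param coeffs named risk slopes per ug/m3.
#' @param threshold SF relative-difference threshold.
#' @param cutoff well-represented cutoff (unused by PHNI; kept for summary
#'   parity).
#' @param minCoverage minimum joint-coverage fraction for a defined SF.
#' @param eps zero-reference floor.
#' @return list per quantity (\code{PM10}, \code{PM2.5}, \code{NO2},
#'   \code{O3}, \code{total}): \code{sf} (list of per-cell vectors, one per
#'   station), \code{r} (per-cell vector) and \code{phni} (scalar).
#' @export
bruteForcePHNI <- function(scenario, coeffs = riskCoefficients(),
                           threshold = 0.2, cutoff = 0.9,
                           minCoverage = 0.75, eps = 1e-9) {
  g <- scenario$config$grid
  nHours <- length(scenario$time)
  if (g@nRows > 50 || g@nCols > 50 || nHours > 2000)
    stop("instance too large for the brute-force reference (max 50x50 cells, 2000 h)")
  nc <- g@nRows * g@nCols

  ## concentrations in ug/m3, cell x hour, by independent arithmetic
  mm <- c(NO2 = 46.0055, O3 = 48.00)
  conc <- list()
  for (p in c("PM10", "PM2.5", "NO2", "O3")) {
    f <- scenario$fields[[p]]
    v <- SummarizedExperiment::assay(f, 1L)
    if (f@unit == "ppb") v <- v * mm[[p]] / 24.45
    conc[[p]] <- v
  }

  ## %AR by scalar loop
  ar <- list()
  for (p in names(conc)) {
    m <- matrix(NA_real_, nc, nHours)
    for (i in seq_len(nc)) for (t in seq_len(nHours)) {
      ci <- conc[[p]][i, t]
      if (!is.na(ci)) m[i, t] <- (exp(coeffs[[p]] * ci) - 1) * 100
    }
    ar[[p]] <- m
  }
  m <- matrix(NA_real_, nc, nHours)
  for (i in seq_len(nc)) for (t in seq_len(nHours)) {
    a25 <- ar[["PM2.5"]][i, t]; a10 <- ar[["PM10"]][i, t]
    an <- ar[["NO2"]][i, t]; ao <- ar[["O3"]][i, t]
    if (!is.na(a25) && !is.na(a10) && !is.na(an) && !is.na(ao))
      m[i, t] <- an + ao + (if (a25 > a10) a25 else a10)
  }
  ar[["total"]] <- m

  popCells <- as.vector(t(scenario$population@counts))
  stations <- scenario$stations

  out <- list()
  for (q in names(ar)) {
    sfList <- list()
    for (s in seq_len(nrow(stations))) {
      scell <- stations$cell[s]
      sf <- rep(NA_real_, nc)
      for (i in seq_len(nc)) {
        nOk <- 0L; nSim <- 0L
        for (t in seq_len(nHours)) {
          a <- ar[[q]][i, t]; b <- ar[[q]][scell, t]
          if (is.na(a) || is.na(b)) next
          nOk <- nOk + 1L
          sim <- if (abs(b) < eps) abs(a - b) < eps else
            abs(a - b) / b <= threshold
          if (sim) nSim <- nSim + 1L
        }
        if (nOk >= minCoverage * nHours) sf[i] <- nSim / nOk
      }
      sf[scell] <- 1
      sfList[[stations$id[s]]] <- sf
    }
    r <- rep(NA_real_, nc)
    for (i in seq_len(nc)) {
      best <- NA_real_
      for (s in seq_along(sfList)) {
        v <- sfList[[s]][i]
        if (!is.na(v) && (is.na(best) || v > best)) best <- v
      }
      r[i] <- best
    }
    num <- 0; den <- 0
    for (i in seq_len(nc)) if (!is.na(r[i])) {
      num <- num + r[i] * popCells[i]
      den <- den + popCells[i]
    }
    out[[q]] <- list(sf = sfList, r = r, phni = num / den)
  }
  out
}
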