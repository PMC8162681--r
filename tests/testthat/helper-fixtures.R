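## Shared in-code fixtures. Everything is generated, nothing stored.

tinyGrid <- function(nCols = 5, nRows = 5, dx = 45, dy = 48)
  GridSpec(0, 0, dx, dy, nCols = nCols, nRows = nRows)

hourAxis <- function(n, start = "2019-01-01 00:00:00")
  as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1)

## an ARField with given cell x hour values on a tiny grid
tinyARField <- function(values, grid = NULL, pollutant = "NO2") {
  values <- as.matrix(values)
  if (is.null(grid)) {
    n <- nrow(values)
    grid <- GridSpec(0, 0, 45, 48, nCols = n, nRows = 1)
  }
  ARField(values, grid, hourAxis(ncol(values)), pollutant)
}

## one mid-grid station record on a given grid
midStation <- function(grid, id = "S1", type = "general") {
  x <- grid@originX + (grid@nCols / 2 - 0.4) * grid@dx
  y <- grid@originY + (grid@nRows / 2 - 0.4) * grid@dy
  locatePseudoStations(
    data.frame(id = id, type = type, x = x, y = y,
               stringsAsFactors = FALSE), grid)
}

uniformPopulation <- function(grid, perCell = 1)
  PopulationRaster(matrix(perCell, grid@nRows, grid@nCols), grid)

## a moderately heterogeneous scenario reused across tests (built once)
SCEN <- generateScenario(ScenarioConfig(
  seed = 42,
  grid = GridSpec(0, 0, 45, 48, nCols = 15, nRows = 15),
  nHours = 240, pmScale = 0.6,
  stationCounts = c(general = 1, roadside = 1)))

## independent point-in-polygon (even-odd ray casting), used as the oracle
## for district assignment
rayCastInside <- function(px, py, rings) {
  inside <- FALSE
  for (r in rings) {
    n <- nrow(r)
    j <- n
    for (i in seq_len(n)) {
      xi <- r[i, 1]; yi <- r[i, 2]; xj <- r[j, 1]; yj <- r[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
  }
  inside
}
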