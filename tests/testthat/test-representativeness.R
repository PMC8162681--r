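mkSF <- function(vals, grid, id = "S1", pollutant = "NO2") {
  new("SFMap", grid = grid, stationId = id, pollutant = pollutant,
      period = "annual", values = matrix(vals, grid@nRows, grid@nCols),
      nValid = matrix(1L, grid@nRows, grid@nCols))
}

test_that("network representativeness is the per-cell maximum over stations", {
  g <- tinyGrid(10, 10)
  set.seed(4)
  maps <- lapply(1:5, function(k)
    mkSF(runif(nCells(g)), g, id = paste0("S", k)))
  # single map: identity
  expect_equal(mapValues(networkRepresentativeness(maps[1])),
               mapValues(maps[[1]]))
  r <- networkRepresentativeness(maps)
  for (i in seq_len(g@nRows)) for (j in seq_len(g@nCols))
    expect_equal(mapValues(r)[i, j],
                 max(vapply(maps, function(m) mapValues(m)[i, j], 0)))
  # NA cells contribute nothing; all-NA cells stay undefined
  m1 <- maps[[1]]; m1@values[1, 1] <- NA
  r2 <- networkRepresentativeness(list(m1, maps[[2]]))
  expect_equal(mapValues(r2)[1, 1], mapValues(maps[[2]])[1, 1])
  onlyNA <- networkRepresentativeness(list(m1))
  expect_true(is.na(mapValues(onlyNA)[1, 1]))
  expect_error(networkRepresentativeness(list()), "at least one")
})

test_that("represented area counts strictly-qualifying cells times cell area", {
  g <- tinyGrid(10, 10)  # 45 x 48 m cells
  v <- rep(0.5, 100); v[1:20] <- 0.95
  m <- mkSF(v, g)
  expect_equal(representedArea(m), 20 * 2160 / 1e6)  # 0.0432 km2
  expect_equal(representedArea(mkSF(rep(0.9, 100), g)), 0)  # strict >
  set.seed(2)
  vr <- runif(100)
  expect_equal(representedArea(mkSF(vr, g), cutoff = 0.6),
               sum(vr > 0.6) * 2160 / 1e6)
})

test_that("represented population is the masked sum over qualifying cells", {
  g <- tinyGrid(10, 10)
  set.seed(6)
  v <- runif(100)
  m <- mkSF(v, g)
  popU <- uniformPopulation(g)
  expect_equal(representedPopulation(m, popU), sum(v > 0.9))
  expect_equal(representedPopulation(mkSF(rep(0.1, 100), g), popU), 0)
  pop <- PopulationRaster(matrix(runif(100, 0, 50), 10, 10), g)
  acc <- 0
  for (i in 1:10) for (j in 1:10)
    if (!is.na(mapValues(m)[i, j]) && mapValues(m)[i, j] > 0.9)
      acc <- acc + mapValues(pop)[i, j]
  expect_equal(representedPopulation(m, pop), acc)
  expect_error(representedPopulation(m, uniformPopulation(tinyGrid(3, 3))),
               "grid")
})

test_that("PHNI is the population-weighted mean of R over the domain", {
  g2 <- GridSpec(0, 0, 45, 48, nCols = 2, nRows = 1)
  rmap <- new("RepresentativenessMap", grid = g2, pollutant = "NO2",
              period = "annual", values = matrix(c(1.0, 0.5), 1, 2))
  pop <- PopulationRaster(matrix(c(3, 1), 1, 2), g2)
  expect_equal(phni(rmap, pop)$phni, 0.875)
  # R = 1 everywhere -> PHNI = 1 whatever the population
  ones <- new("RepresentativenessMap", grid = g2, pollutant = "NO2",
              period = "annual", values = matrix(1, 1, 2))
  expect_equal(phni(ones, pop)$phni, 1)
  # uniform population: weights cancel, PHNI = mean(R)
  g <- tinyGrid(20, 20)
  set.seed(19)
  vals <- matrix(runif(400), 20, 20)
  rr <- new("RepresentativenessMap", grid = g, pollutant = "O3",
            period = "annual", values = vals)
  expect_equal(phni(rr, uniformPopulation(g))$phni, mean(vals))
  # random case matches a scalar weighted-mean loop; undefined R excluded
  vals[3, 7] <- NA
  rrNA <- new("RepresentativenessMap", grid = g, pollutant = "O3",
              period = "annual", values = vals)
  w <- PopulationRaster(matrix(runif(400, 0, 10), 20, 20), g)
  num <- 0; den <- 0
  for (i in 1:20) for (j in 1:20) if (!is.na(vals[i, j])) {
    num <- num + vals[i, j] * mapValues(w)[i, j]
    den <- den + mapValues(w)[i, j]
  }
  res <- phni(rrNA, w)
  expect_equal(res$phni, num / den)
  expect_equal(res$population, den)
  expect_gte(res$phni, 0); expect_lte(res$phni, 1)
  # zero-population domain is an error
  zero <- PopulationRaster(matrix(0, 20, 20), g)
  expect_error(phni(rrNA, zero), "zero population")
})

test_that("seasonal masks partition a calendar year", {
  expect_true(seasonalPeriods(as.POSIXct("2019-07-15 10:00",
                                         tz = "UTC"))$summer)
  expect_true(seasonalPeriods(as.POSIXct("2019-12-01 00:00",
                                         tz = "UTC"))$winter)
  tm <- hourAxis(8760, "2019-01-01 00:00:00")
  m <- seasonalPeriods(tm)
  expect_true(all(m$annual))
  seas <- cbind(m$spring, m$summer, m$autumn, m$winter)
  expect_true(all(rowSums(seas) == 1))  # partition
  expect_equal(sum(m$spring), (31 + 30 + 31) * 24)   # Mar-May
  expect_equal(sum(m$summer), (30 + 31 + 31) * 24)   # Jun-Aug
  expect_equal(sum(m$autumn), (30 + 31 + 30) * 24)   # Sep-Nov
  expect_equal(sum(m$winter), (31 + 28 + 31) * 24)   # Dec + Jan-Feb
  expect_error(seasonalPeriods(hourAxis(24 * 400)), "multiple years")
})

test_that("district PHNI assigns cells by centroid containment", {
  g <- tinyGrid(10, 10)
  set.seed(23)
  vals <- matrix(runif(100), 10, 10)
  rmap <- new("RepresentativenessMap", grid = g, pollutant = "total",
              period = "annual", values = vals)
  pop <- PopulationRaster(matrix(runif(100, 0, 10), 10, 10), g)
  # one district covering the whole grid equals the global PHNI
  whole <- list(all = list(rbind(c(-1, -1), c(1000, -1), c(1000, 1000),
                                 c(-1, 1000), c(-1, -1))))
  expect_equal(districtPHNI(rmap, pop, whole)$phni, phni(rmap, pop)$phni)
  # two half-grids with R = 1 and R = 0.5 under uniform population
  half <- matrix(0.5, 10, 10); half[, 1:5] <- 1
  rHalf <- new("RepresentativenessMap", grid = g, pollutant = "total",
               period = "annual", values = half)
  splitAt <- 5 * g@dx
  polys <- list(west = list(rbind(c(0, 0), c(splitAt, 0), c(splitAt, 480),
                                  c(0, 480), c(0, 0))),
                east = list(rbind(c(splitAt, 0), c(450, 0), c(450, 480),
                                  c(splitAt, 480), c(splitAt, 0))))
  dres <- districtPHNI(rHalf, uniformPopulation(g), polys)
  expect_equal(dres$phni[dres$domain == "west"], 1)
  expect_equal(dres$phni[dres$domain == "east"], 0.5)
  # random triangle: membership matches an independent ray-casting loop
  tri <- list(rbind(c(30, 20), c(430, 100), c(150, 460), c(30, 20)))
  cc <- cellCenters(g)
  oracle <- vapply(seq_len(nrow(cc)),
                   function(i) rayCastInside(cc$x[i], cc$y[i], tri),
                   logical(1))
  got <- districtPHNI(rmap, pop, list(tri = tri))
  num <- sum(vals[cbind(cc$row, cc$col)][oracle] *
               mapValues(pop)[cbind(cc$row, cc$col)][oracle])
  den <- sum(mapValues(pop)[cbind(cc$row, cc$col)][oracle])
  expect_equal(got$phni, num / den)
  # a district with no population is NA, not an error
  empty <- list(out = list(rbind(c(5000, 5000), c(5100, 5000),
                                 c(5100, 5100), c(5000, 5000))))
  expect_true(is.na(districtPHNI(rmap, pop, empty)$phni))
})

test_that("area-population correlation matches the textbook sum formula", {
  s <- data.frame(station_id = sprintf("S%02d", 1:15),
                  area_km2 = NA, population = NA)
  set.seed(31)
  s$area_km2 <- runif(15, 0, 100)
  s$population <- 1000 * s$area_km2 + rnorm(15, 0, 2e4)
  res <- areaPopulationCorrelation(s)
  a <- s$area_km2; p <- s$population; n <- 15
  rHand <- (n * sum(a * p) - sum(a) * sum(p)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(p^2) - sum(p)^2))
  expect_equal(res$r, rHand)
  expect_equal(res$n, 15)
  # perfect and anti-ordered cases
  s2 <- data.frame(station_id = c("A", "B", "C"), area_km2 = c(1, 2, 3),
                   population = c(1, 2, 3))
  expect_equal(areaPopulationCorrelation(s2)$r, 1)
  s2$population <- c(3, 2, 1)
  expect_equal(areaPopulationCorrelation(s2)$r, -1)
  # exclusion list drops a station before correlating
  s3 <- rbind(s, data.frame(station_id = "BG", area_km2 = 500,
                            population = 0))
  expect_equal(areaPopulationCorrelation(s3, exclude = "BG")$r, rHand)
  # zero variance reported as undefined
  s2$area_km2 <- c(1, 1, 1)
  expect_true(is.na(areaPopulationCorrelation(s2)$r))
  expect_error(areaPopulationCorrelation(s2[1:2, ]), "at least 3")
})

test_that("adding a station never decreases R or PHNI", {
  g <- SCEN$config$grid
  ar <- computeARFields(SCEN$fields)
  pop <- SCEN$population
  maps <- lapply(seq_len(nrow(SCEN$stations)), function(s)
    sfMap(ar$NO2, SCEN$stations[s, , drop = FALSE]))
  r1 <- networkRepresentativeness(maps[1])
  r12 <- networkRepresentativeness(maps)
  d <- mapValues(r12) - mapValues(r1)
  expect_true(all(d >= 0, na.rm = TRUE))
  expect_gte(phni(r12, pop)$phni, phni(r1, pop)$phni)
})
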