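test_that("scenario generation is deterministic given the seed", {
  cfg <- ScenarioConfig(seed = 77, grid = tinyGrid(8, 8), nHours = 48)
  a <- generateScenario(cfg)
  b <- generateScenario(cfg)
  for (p in names(a$fields))
    expect_identical(fieldValues(a$fields[[p]]), fieldValues(b$fields[[p]]))
  expect_identical(a$stations, b$stations)
  expect_identical(mapValues(a$population), mapValues(b$population))
  # a different seed gives different fields
  c2 <- generateScenario(ScenarioConfig(seed = 78, grid = tinyGrid(8, 8),
                                        nHours = 48))
  expect_false(identical(fieldValues(a$fields$NO2),
                         fieldValues(c2$fields$NO2)))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generateScenario(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("without local sources or spatial noise every field is homogeneous", {
  cfg <- ScenarioConfig(seed = 5, grid = tinyGrid(8, 8), nHours = 48,
                        sources = list(), spatialNoiseSdFrac = 0,
                        stationCounts = c(general = 1))
  scen <- generateScenario(cfg)
  for (p in names(scen$fields)) {
    v <- fieldValues(scen$fields[[p]])
    expect_equal(max(apply(v, 2, function(col) diff(range(col)))), 0)
  }
  # any single station then represents everything: SF = 1, PHNI = 1
  res <- evaluateScenario(scen, quantities = c("NO2", "total"),
                          periods = "annual")
  expect_true(all(mapValues(res$NO2$sfMaps$annual[[1]]) == 1))
  expect_equal(res$NO2$phniTable$phni, rep(1, 5))
  expect_equal(res$total$phniTable$phni, rep(1, 5))
})

test_that("ox-conserved mode keeps NO2 + O3 spatially constant per hour", {
  # moderate plumes: titration never drives O3 to zero, so conservation
  # is exact cell-to-cell
  g <- GridSpec(0, 0, 45, 48, nCols = 20, nRows = 20)
  src <- defaultSources(g)
  for (i in seq_along(src)) src[[i]]$strength <- 10
  scen <- generateScenario(ScenarioConfig(seed = 9, grid = g, nHours = 240,
                                          sources = src))
  ox <- fieldValues(scen$fields$NO2) + fieldValues(scen$fields$O3)
  rng <- apply(ox, 2, function(v) diff(range(v)))
  expect_true(all(rng <= 0.01 * colMeans(ox)))
  # and NO2/O3 are anticorrelated across space within an hour
  no2 <- fieldValues(scen$fields$NO2)
  hr <- which.max(apply(no2, 2, sd))
  expect_lt(cor(no2[, hr], fieldValues(scen$fields$O3)[, hr]), -0.99)
  # with default (stronger) plumes, hours without clipped O3 still
  # conserve Ox exactly
  scen2 <- generateScenario(ScenarioConfig(seed = 9, grid = g, nHours = 240))
  o3 <- fieldValues(scen2$fields$O3)
  ox2 <- fieldValues(scen2$fields$NO2) + o3
  unclipped <- apply(o3, 2, function(v) all(v > 0))
  expect_true(any(unclipped))
  rng2 <- apply(ox2[, unclipped, drop = FALSE], 2,
                function(v) diff(range(v)))
  expect_true(all(rng2 < 1e-9 * mean(ox2)))
})

test_that("invalid configurations are rejected by field name", {
  expect_error(ScenarioConfig(), "seed")
  expect_error(ScenarioConfig(seed = 1, ar1Phi = 1), "ar1Phi")
  expect_error(ScenarioConfig(seed = 1, noiseSdFrac = -1), "noise sd")
  expect_error(ScenarioConfig(seed = 1,
                              pmRegionalFraction = c(PM10 = 2, `PM2.5` = 0.4)),
               "pmRegionalFraction")
  expect_error(ScenarioConfig(seed = 1,
                              population = list(nClusters = 2,
                                                clusterSd = 100,
                                                total = 0)),
               "population total")
  badSrc <- list(list(pollutant = "NO2", type = "point", x = 0, y = 0,
                      strength = 5, decay = -1))
  expect_error(ScenarioConfig(seed = 1, sources = badSrc), "decay")
})

test_that("the brute-force reference behaves on its analytic cases", {
  # homogeneous scenario: PHNI 1 for every quantity
  cfg <- ScenarioConfig(seed = 2, grid = tinyGrid(6, 6), nHours = 36,
                        sources = list(), stationCounts = c(general = 1))
  scen <- generateScenario(cfg)
  bf <- bruteForcePHNI(scen)
  for (q in names(bf)) expect_equal(bf[[q]]$phni, 1)
  # single station: PHNI equals the population-weighted mean of its SF map
  scen2 <- generateScenario(ScenarioConfig(seed = 3, grid = tinyGrid(6, 6),
                                           nHours = 36,
                                           stationCounts = c(general = 1)))
  bf2 <- bruteForcePHNI(scen2)
  pop <- as.vector(t(mapValues(scen2$population)))
  sf <- bf2$NO2$sf[[1]]
  expect_equal(bf2$NO2$phni, sum(sf * pop) / sum(pop))
  # refuses instances beyond its intended size
  big <- generateScenario(ScenarioConfig(seed = 1,
                                         grid = tinyGrid(60, 60),
                                         nHours = 2))
  expect_error(bruteForcePHNI(big), "too large")
})

test_that("stronger local sources degrade a fixed network's PHNI on average", {
  meanPHNI <- function(strength) {
    vals <- vapply(1:3, function(s) {
      g <- GridSpec(0, 0, 45, 48, nCols = 12, nRows = 12)
      src <- defaultSources(g)
      for (i in seq_along(src)) src[[i]]$strength <- strength
      scen <- generateScenario(ScenarioConfig(
        seed = 100 + s, grid = g, nHours = 120, sources = src,
        stationCounts = c(general = 1)))
      res <- evaluateScenario(scen, quantities = "NO2", periods = "annual",
                              useDistricts = FALSE)
      res$NO2$phniTable$phni[1]
    }, numeric(1))
    mean(vals)
  }
  expect_gte(meanPHNI(2), meanPHNI(40))
})
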