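meshRow <- function(x, y, value, tm, pollutant = "NO2")
  data.frame(x = x, y = y, pollutant = pollutant, timestamp = tm,
             value = value, stringsAsFactors = FALSE)

test_that("rasterization averages the mesh points inside each cell", {
  g <- tinyGrid()
  tm <- hourAxis(1)
  # one point -> its own value; all other cells missing
  f1 <- rasterizeMesh(meshRow(10, 10, 7.0, tm), g, "NO2", unit = "ppb")
  v <- fieldValues(f1)
  expect_equal(v[1, 1], 7.0)
  expect_equal(sum(!is.na(v)), 1L)
  # two points in one cell -> their mean
  f2 <- rasterizeMesh(rbind(meshRow(10, 10, 2, tm), meshRow(20, 20, 4, tm)),
                      g, "NO2", unit = "ppb")
  expect_equal(fieldValues(f2)[1, 1], 3.0)
})

test_that("rasterization matches a brute-force per-cell accumulation", {
  g <- tinyGrid(5, 5)
  set.seed(21)
  nPts <- 200
  tm <- hourAxis(3)
  mesh <- do.call(rbind, lapply(seq_along(tm), function(t)
    data.frame(x = runif(nPts, 0, g@nCols * g@dx),
               y = runif(nPts, 0, g@nRows * g@dy),
               pollutant = "PM10", timestamp = tm[t],
               value = runif(nPts, 0, 50))))
  f <- rasterizeMesh(mesh, g, "PM10")
  v <- fieldValues(f)
  cc <- cellCenters(g)
  for (i in seq_len(nCells(g))) for (t in seq_along(tm)) {
    x0 <- g@originX + (cc$col[i] - 1) * g@dx
    y0 <- g@originY + (cc$row[i] - 1) * g@dy
    sub <- mesh[mesh$timestamp == tm[t] &
                  mesh$x >= x0 & mesh$x < x0 + g@dx &
                  mesh$y >= y0 & mesh$y < y0 + g@dy, ]
    if (nrow(sub) == 0) expect_true(is.na(v[i, t]))
    else expect_equal(v[i, t], mean(sub$value))
  }
})

test_that("rasterization rejects empty and malformed meshes", {
  g <- tinyGrid()
  tm <- hourAxis(1)
  expect_error(rasterizeMesh(meshRow(10, 10, 1, tm, "O3"), g, "NO2"),
               "no points")
  expect_error(rasterizeMesh(meshRow(-1000, -1000, 1, tm), g, "NO2"),
               "no in-domain")
  expect_error(rasterizeMesh(meshRow(Inf, 10, 1, tm), g, "NO2"), "point 1")
})

test_that("nearest-cell fill is off by default and fills when requested", {
  g <- tinyGrid(3, 1)
  tm <- hourAxis(2)
  mesh <- rbind(meshRow(10, 10, c(5), tm[1]), meshRow(10, 10, 6, tm[2]))
  f <- rasterizeMesh(mesh, g, "NO2", unit = "ppb")
  expect_true(all(is.na(fieldValues(f)[2:3, ])))
  ff <- rasterizeMesh(mesh, g, "NO2", unit = "ppb", fillNearest = TRUE)
  expect_equal(fieldValues(ff)[3, ], c(5, 6))
})

test_that("pseudo-station location follows the cell-intersection rule", {
  g <- tinyGrid(20, 20)
  set.seed(5)
  st <- data.frame(id = sprintf("S%02d", 1:10),
                   type = rep("general", 10),
                   x = runif(10, 0, g@nCols * g@dx),
                   y = runif(10, 0, g@nRows * g@dy),
                   stringsAsFactors = FALSE)
  loc <- locatePseudoStations(st, g)
  expect_equal(loc$col, as.integer(floor(st$x / g@dx) + 1))
  expect_equal(loc$row, as.integer(floor(st$y / g@dy) + 1))
  # duplicate ids rejected
  expect_error(locatePseudoStations(rbind(st, st[1, ]), g), "duplicate")
  # out-of-domain stations excluded with a warning
  st$x[4] <- -999
  expect_warning(loc2 <- locatePseudoStations(st, g), "S04")
  expect_equal(nrow(loc2), 9)
})

test_that("population resampling conserves totals and matches a nearest-centre loop", {
  fine <- tinyGrid(30, 30, dx = 10, dy = 10)
  # identity: same grid in and out
  pop <- PopulationRaster(matrix(runif(900, 0, 5), 30, 30), fine)
  same <- resamplePopulation(pop, fine)
  expect_equal(mapValues(same), mapValues(pop))

  # one coarse cell split equally among the fine cells it covers
  coarse1 <- GridSpec(0, 0, 463, 10, nCols = 1, nRows = 1)
  fine1 <- GridSpec(0, 0, 1, 10, nCols = 463, nRows = 1)
  r1 <- resamplePopulation(PopulationRaster(matrix(463, 1, 1), coarse1),
                           fine1)
  expect_true(all(mapValues(r1) == 1.0))
  expect_equal(sum(mapValues(r1)), 463)

  # random 3x3 coarse over 30x30 fine: conservation + per-cell oracle
  cg <- GridSpec(0, 0, 100, 100, nCols = 3, nRows = 3)
  set.seed(9)
  cpop <- PopulationRaster(matrix(runif(9, 0, 1000), 3, 3), cg)
  out <- resamplePopulation(cpop, fine)
  expect_equal(sum(mapValues(out)), sum(mapValues(cpop)), tolerance = 1e-6)
  cc <- cellCenters(fine)
  ccoarse <- cellCenters(cg)
  near <- integer(nrow(cc))
  for (i in seq_len(nrow(cc)))
    near[i] <- which.min((ccoarse$x - cc$x[i])^2 + (ccoarse$y - cc$y[i])^2)
  mult <- tabulate(near, 9)
  coarseCells <- as.vector(t(mapValues(cpop)))
  expect_equal(as.vector(t(mapValues(out))), coarseCells[near] / mult[near])

  # disjoint extents and CRS mismatch are errors
  far <- GridSpec(1e6, 1e6, 10, 10, nCols = 5, nRows = 5)
  expect_error(resamplePopulation(cpop, far), "disjoint")
  otherCrs <- GridSpec(0, 0, 10, 10, nCols = 5, nRows = 5, crs = "EPSG:32650")
  expect_error(resamplePopulation(cpop, otherCrs), "CRS")
})
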