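test_that("daily-to-monthly radiation conversion uses calendar lengths", {
  expect_equal(convertRadiation(1e6, 6), 30)
  expect_equal(convertRadiation(0, 3), 0)
  expect_equal(convertRadiation(2e6, 2), 56)       # 28-day February
  expect_equal(convertRadiation(1e6, 1), 31)
})

test_that("kriging with zero nugget is exact at station cells", {
  g <- gridGeoref(20L, 20L, cellsize = 10)
  ## stations placed exactly at cell centers
  set.seed(4)
  rows <- c(3L, 8L, 15L, 18L, 6L)
  cols <- c(4L, 12L, 7L, 16L, 18L)
  st <- data.frame(
    lon = g$xll + (cols - 0.5) * g$cellsize,
    lat = g$yll + (g$nrow - rows + 0.5) * g$cellsize,
    v = rnorm(5L, 50, 8))
  kr <- interpolateGrid(st, "v", g, method = "kriging")
  for (i in seq_len(5L))
    expect_equal(kr[rows[i], cols[i]], st$v[i], tolerance = 1e-6)
})

test_that("kriging reproduces a linear field at interior points", {
  g <- gridGeoref(21L, 21L, cellsize = 10)
  xs <- c(5, 105, 205, 15, 195, 105, 55, 155)
  ys <- c(5, 15, 5, 195, 205, 105, 155, 55)
  st <- data.frame(lon = xs, lat = ys, v = 2 + 0.03 * xs + 0.01 * ys)
  kr <- interpolateGrid(st, "v", g, method = "kriging")
  ## midpoint cell (row/col center): compare with the linear prediction
  cx <- g$xll + (10 + 0.5) * g$cellsize
  cy <- g$yll + (g$nrow - 11 + 0.5) * g$cellsize
  expect_equal(kr[11L, 11L], 2 + 0.03 * cx + 0.01 * cy, tolerance = 0.2)
})

test_that("IDW stays within station bounds and handles one station", {
  g <- gridGeoref(10L, 10L, cellsize = 10)
  one <- data.frame(lon = 35, lat = 35, v = 7)
  expect_equal(interpolateGrid(one, "v", g, method = "idw"),
               matrix(7, 10L, 10L))
  set.seed(9)
  st <- data.frame(lon = runif(6, 0, 100), lat = runif(6, 0, 100),
                   v = rnorm(6))
  idw <- interpolateGrid(st, "v", g, method = "idw")
  expect_true(all(idw >= min(st$v) - 1e-12 & idw <= max(st$v) + 1e-12))
  expect_error(interpolateGrid(st[1:2, ], "v", g, method = "kriging"),
               "at least 3")
})

test_that("interpolation is deterministic given inputs", {
  g <- gridGeoref(12L, 12L, cellsize = 10)
  set.seed(13)
  st <- data.frame(lon = runif(5, 0, 120), lat = runif(5, 0, 120),
                   v = rnorm(5, 10))
  expect_identical(interpolateGrid(st, "v", g, "kriging"),
                   interpolateGrid(st, "v", g, "kriging"))
})

test_that("station CSV routes through conversion and interpolation", {
  g <- gridGeoref(8L, 8L, cellsize = 10)
  st <- expand.grid(station_id = 1:4, month = c(6L, 7L))
  set.seed(2)
  st$lon <- rep(c(15, 65, 25, 55), 2L)
  st$lat <- rep(c(15, 25, 65, 55), 2L)
  st$sol_daily <- 1.4e7 + rnorm(8, sd = 1e5)
  st$temp <- 22 + rnorm(8)
  st$precip <- 120 + rnorm(8, sd = 5)
  mg <- stationsToMeteo(st, g, method = "idw")
  expect_setequal(names(mg), c("6", "7"))
  expect_s4_class(mg[["6"]], "MeteoGrid")
  ## radiation was converted to MJ/m2/month
  expect_true(all(mg[["6"]]@sol > 300 & mg[["6"]]@sol < 500))
  expect_error(stationsToMeteo(st[, -5L], g), "sol")
})
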