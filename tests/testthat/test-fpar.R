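test_that("min-max normalization, idempotence and exact round-trip", {
  fm <- featureMatrix(cbind(a = c(2, 4, 6), b = c(0, 0.5, 1)))
  nm <- normalizeFeatures(fm)
  expect_equal(unname(nm$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nm$values[, "b"]), c(0, 0.5, 1))   # already [0,1]
  ## round-trip on new data
  new <- cbind(a = c(2.5, 5.5), b = c(0.2, 0.9))
  back <- invertScaling(applyScaling(new, nm$scaling), nm$scaling)
  expect_equal(back, new, tolerance = 1e-12, ignore_attr = TRUE)
  ## constant feature dropped with warning
  fm2 <- featureMatrix(cbind(a = c(1, 2, 3), c = c(5, 5, 5)))
  expect_warning(n2 <- normalizeFeatures(fm2), "constant")
  expect_equal(n2$featureNames, "a")
})

test_that("RFE recovers a dominant feature and handles edge cases", {
  set.seed(10)
  n <- 400L
  X <- matrix(rnorm(n * 6L), n, 6L)
  colnames(X) <- c("DVI", "N1", "N2", "N3", "N4", "N5")
  y <- 3 * X[, "DVI"] + rnorm(n, sd = 1e-3)
  fm <- featureMatrix(X)
  r <- rfeRank(fm, y, nKeep = 2L, seed = 1L)
  expect_equal(r$ranking[["DVI"]], 1L)
  expect_equal(r$selected[1L], "DVI")
  expect_length(r$scores, 5L)           # one CV score per set size 6..2

  ## no elimination: all features selected, ranking a permutation of 1..6
  rAll <- rfeRank(fm, y, nKeep = 6L, seed = 1L)
  expect_setequal(rAll$selected, colnames(X))
  expect_setequal(rAll$ranking, 1:6)

  ## duplicated informative column: exactly one of the pair survives
  X2 <- cbind(X[, 1:4], DVI_dup = X[, "DVI"])
  r2 <- rfeRank(featureMatrix(X2), y, nKeep = 2L, seed = 1L)
  expect_equal(sum(c("DVI", "DVI_dup") %in% r2$selected), 1L)

  expect_error(rfeRank(fm, y, nKeep = 0L), "nKeep")
  expect_error(rfeRank(fm, y, nKeep = 9L), "nKeep")
})

test_that("tree baselines fit easy targets and are seed-deterministic", {
  set.seed(12)
  n <- 500L
  X <- matrix(runif(n * 4L), n, 4L)
  colnames(X) <- c("DVI", "NDVI", "RVI", "SAVI")
  fm <- featureMatrix(X)
  ## constant target
  mc <- trainFparTree(fm, rep(0.4, n), kind = "gbdt", nrounds = 50L)
  expect_lte(mc$report@mae, 0.01)
  ## linear single-feature target
  y <- 0.1 + 0.8 * X[, "DVI"]
  ml <- trainFparTree(fm, y, kind = "xgb", nrounds = 200L)
  expect_gte(ml$report@r2, 0.95)
  ## determinism
  m1 <- trainFparTree(fm, y, kind = "gbdt", nrounds = 50L, seed = 3L)
  m2 <- trainFparTree(fm, y, kind = "gbdt", nrounds = 50L, seed = 3L)
  expect_identical(reportAsList(m1$report), reportAsList(m2$report))
})

test_that("predictFpar clips, validates features, and matches grid/vector paths", {
  d <- fparMappingData(n = 600L)
  m <- trainFparCnn(d$features, d$y, cnnConfig(epochs = 3L, seed = 4L))
  ## clip contract: predictions stay inside [0,1] even for extreme inputs
  ext <- d$features$values
  ext[1L, ] <- ext[1L, ] * 10
  p <- predictFpar(m, featureMatrix(ext))
  expect_true(all(p >= 0 & p <= 1))

  ## missing feature is a named error
  bad <- d$features$values[, -3L]
  expect_error(predictFpar(m, featureMatrix(bad, colnames(bad))), "EVI")

  ## grid prediction equals the vector prediction reshaped
  sc <- tinyScene()
  cube <- computeIndices(sceneStack(sc, 7L))
  field <- predictFpar(m, cube)
  ft <- cubeToFeatures(cube)
  vec <- predictFpar(m, featureMatrix(ft$values, ft$featureNames))
  expect_equal(fparValues(field)[ft$pixelIndex], vec, tolerance = 1e-12)
  expect_s4_class(field, "FparField")
})

test_that("empirical NDVI/RVI FPAR honors stretch boundaries and the blend", {
  p <- empiricalFparParams(ndvi_min = 0.1, ndvi_max = 0.8, sr_min = 1,
                           sr_max = 8)
  ## upper boundary -> fpar_max, lower -> fpar_min
  up <- empiricalFpar(matrix(0.8, 1L, 1L), matrix(8, 1L, 1L), p)
  expect_equal(fparValues(up)[1L, 1L], 0.95)
  lo <- empiricalFpar(matrix(0.1, 1L, 1L), matrix(1, 1L, 1L), p)
  expect_equal(fparValues(lo)[1L, 1L], 0.001)
  ## alpha = 1 uses NDVI only
  p1 <- empiricalFparParams(ndvi_min = 0.1, ndvi_max = 0.8, sr_min = 1,
                            sr_max = 8, alpha = 1)
  mid <- empiricalFpar(matrix(0.45, 1L, 1L), matrix(2, 1L, 1L), p1)
  expect_equal(fparValues(mid)[1L, 1L],
               (0.45 - 0.1) / (0.8 - 0.1) * (0.95 - 0.001) + 0.001)
  ## bounds must be ordered
  expect_error(empiricalFparParams(ndvi_min = 0.8, ndvi_max = 0.1), "ndvi_max")
  ## outputs bounded for arbitrary inputs
  set.seed(14)
  nd <- matrix(runif(100, -1, 1), 10L, 10L)
  rv <- matrix(runif(100, 0, 20), 10L, 10L)
  f <- fparValues(empiricalFpar(nd, rv, p))
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
})
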