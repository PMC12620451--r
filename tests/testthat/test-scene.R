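test_that("same seed gives an identical scene; different seeds differ", {
  cfg <- sceneConfig(nrow = 10L, ncol = 10L, seed = 3L)
  s1 <- generateScene(cfg)
  s2 <- generateScene(cfg)
  expect_identical(getBand(sceneStack(s1, 7L), "B8"),
                   getBand(sceneStack(s2, 7L), "B8"))
  expect_identical(nppAnnual(sceneNpp(s1)), nppAnnual(sceneNpp(s2)))
  s3 <- generateScene(sceneConfig(nrow = 10L, ncol = 10L, seed = 4L))
  expect_false(identical(getBand(sceneStack(s1, 7L), "B8"),
                         getBand(sceneStack(s3, 7L), "B8")))
})

test_that("a bare-soil scene has zero FPAR and NPP and soil reflectance", {
  cfg <- sceneConfig(nrow = 6L, ncol = 6L,
                     classFractions = c(soil = 1), noiseSigma = 0,
                     seed = 2L)
  sc <- generateScene(cfg)
  expect_true(all(fparValues(sceneFpar(sc, 7L)) == 0))
  expect_true(all(nppAnnual(sceneNpp(sc)) == 0))
  expect_equal(getBand(sceneStack(sc, 7L), "B4"),
               matrix(0.20, 6L, 6L), tolerance = 1e-12)
})

test_that("FPAR saturates with LAI per Beer-Lambert and peaks mid-season", {
  sc <- tinyScene()
  corn <- sceneClassMap(sc) == "corn"
  julyF <- fparValues(sceneFpar(sc, 7L))
  aprF <- fparValues(sceneFpar(sc, 4L))
  expect_true(all(julyF[corn] > aprF[corn]))
  expect_true(all(julyF >= 0 & julyF <= 1))
  ## huge LAI -> FPAR ~ 1
  cfg <- sceneConfig(nrow = 4L, ncol = 4L,
                     classFractions = c(corn = 1),
                     laiCurves = list(corn = list(peak = 60, peakMonth = 7,
                                                  width = 2, rate = 2)),
                     noiseSigma = 0, seed = 5L)
  scBig <- generateScene(cfg)
  expect_true(all(fparValues(sceneFpar(scBig, 7L)) > 0.999))
})

test_that("NDVI separates canopy from bare soil on clean scenes", {
  sc <- tinyScene()
  cube <- computeIndices(sceneStack(sc, 7L))
  nd <- indexLayer(cube, "NDVI")
  soil <- sceneClassMap(sc) == "soil"
  expect_gt(min(nd[!soil], na.rm = TRUE), max(nd[soil], na.rm = TRUE))
})

test_that("stored truth NPP is self-consistent with the forward model", {
  sc <- tinyScene()
  rec <- runCasa(sc@fpar, sc@meteo, sceneTopt(sc),
                 epsilonMax = sc@config$epsilonMax,
                 season = sc@config$season, lat = sc@config$lat)
  expect_lte(max(abs(nppAnnual(rec) - nppAnnual(sceneNpp(sc)))), 1e-9)
})

test_that("cloud injection flags the requested fraction and spares the truth", {
  base <- generateScene(sceneConfig(nrow = 12L, ncol = 12L, seed = 6L))
  ## zero fraction: unchanged
  c0 <- injectClouds(base, months = 7L, patchFraction = 0, seed = 8L)
  expect_identical(getBand(sceneStack(c0, 7L), "B2"),
                   getBand(sceneStack(base, 7L), "B2"))
  ## full cover: every pixel flagged
  c1 <- injectClouds(base, months = 7L, patchFraction = 1, seed = 8L)
  expect_true(all(sceneCloudMask(c1, 7L)))
  ## partial cover: close to target, bright blue, truth untouched
  cp <- injectClouds(base, months = 7L, patchFraction = 0.3, seed = 8L)
  frac <- mean(sceneCloudMask(cp, 7L))
  expect_lte(abs(frac - 0.3), 0.05)
  mask <- sceneCloudMask(cp, 7L)
  expect_gt(mean(getBand(sceneStack(cp, 7L), "B2")[mask]), 0.35)
  expect_identical(fparValues(sceneFpar(cp, 7L)),
                   fparValues(sceneFpar(base, 7L)))
  expect_identical(nppAnnual(sceneNpp(cp)), nppAnnual(sceneNpp(base)))
  ## unknown month is a named error
  expect_error(injectClouds(base, months = 2L), "not present")
})

test_that("training sets pair indices with true FPAR and respect size", {
  sc <- tinyScene()
  tr <- buildTrainingSet(sc, nSamples = 300L, seed = 9L)
  expect_equal(nrow(tr$features$values), 300L)
  expect_equal(tr$features$featureNames, indexNames())
  expect_true(all(tr$y >= 0 & tr$y <= 1))
  expect_setequal(unique(tr$month), sc@config$season)
  ## labels really come from the truth grids
  i <- 17L
  m <- as.character(tr$month[i])
  expect_equal(tr$y[i], fparValues(sc@fpar[[m]])[tr$pixelIndex[i]])
})
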