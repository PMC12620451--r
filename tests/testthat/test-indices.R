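## Independent scalar re-implementation of each index formula, written
## directly from the definitions and kept deliberately separate from the
## package's vectorized evaluation path.
oracleIndex <- function(name, b, a = 0.08, s = 1.2, X = 0.08, L = 0.5) {
  with(as.list(b), switch(name,
    ARVI  = { rb <- 2 * B4 - B2; (B8 - rb) / (B8 + rb) },
    DVI   = B8 - B4,
    EVI   = 2.5 * (B8 - B4) / (B8 + 6 * B4 - 7.5 * B2 + 1),
    GEMI  = {
      n <- (2 * (B8A^2 - B4^2) + 1.5 * B8A + 0.5 * B4) / (B8A + B4 + 0.5)
      n * (1 - 0.25 * n) - (B4 - 0.125) / (1 - B4)
    },
    GNDVI = (B7 - B3) / (B7 + B3),
    MSAVI = (2 * B8 + 1 - sqrt((2 * B8 + 1)^2 - 8 * (B8 - B4))) / 2,
    NDI45 = (B5 - B4) / (B5 + B4),
    NDVI  = (B8 - B4) / (B8 + B4),
    PVI   = (B8 - s * B4 - a) / sqrt(s^2 + 1),
    RVI   = B8 / B4,
    REIP  = 705 + 35 * ((B4 + B7) / 2 - B5) / (B6 - B5),
    SAVI  = (1 + L) * (B8 - B4) / (B8 + B4 + L),
    TNDVI = sqrt((B8 - B4) / (B8 + B4) + 0.5),
    TSAVI = s * (B8 - s * B4 - a) /
      (a * B8 + B4 - a * s + X * (1 + s^2)),
    WDVI  = B8 - s * B4
  ))
}

test_that("hand-evaluated spot checks match the formulas", {
  st <- uniformStack(list(B2 = 0.05, B4 = 0.08, B8 = 0.40))
  expect_equal(computeIndex(st, "NDVI")[1L, 1L], 0.666667, tolerance = 1e-6)

  st2 <- uniformStack(list(B4 = 0.10, B8 = 0.40))
  expect_equal(computeIndex(st2, "RVI")[1L, 1L], 4.0)

  st3 <- uniformStack(list(B4 = 0.05, B5 = 0.10, B6 = 0.20, B7 = 0.25))
  expect_equal(computeIndex(st3, "REIP")[1L, 1L], 722.5)

  ## zero numerator
  st4 <- uniformStack(list(B4 = 0.3, B8 = 0.3))
  expect_true(all(computeIndex(st4, "NDVI") == 0))

  ## SAVI with L = 0 degenerates to NDVI
  stR <- randomBandStack(50L)
  p0 <- indexParams(savi_L = 0)
  expect_equal(computeIndex(stR, "SAVI", p0), computeIndex(stR, "NDVI", p0),
               tolerance = 1e-12)
})

test_that("every index matches the independent oracle on random bands", {
  n <- 200L
  st <- randomBandStack(n)
  vecs <- sapply(bandNames(), function(b) as.vector(getBand(st, b)))
  for (nm in indexNames()) {
    got <- as.vector(computeIndex(st, nm))
    want <- suppressWarnings(   # oracle sqrt goes NaN where the package masks
      vapply(seq_len(n), function(i) oracleIndex(nm, vecs[i, ]), numeric(1)))
    ok <- !is.na(got)
    expect_true(all(abs(got[ok] - want[ok]) <= 1e-10),
                label = paste("oracle equivalence for", nm))
  }
})

test_that("normalized-difference indices are bounded and NDVI is monotone", {
  st <- randomBandStack(300L, seed = 5L)
  for (nm in c("NDVI", "GNDVI", "NDI45")) {
    v <- computeIndex(st, nm)
    expect_true(all(v >= -1 & v <= 1, na.rm = TRUE), label = nm)
  }
  ## NDVI strictly increasing in B8 at fixed B4 > 0
  b8 <- seq(0.05, 0.6, length.out = 40L)
  st2 <- reflectanceStack(list(B4 = matrix(0.1, 1L, 40L),
                               B8 = matrix(b8, 1L, 40L)), month = 6L)
  nd <- as.vector(computeIndex(st2, "NDVI"))
  expect_true(all(diff(nd) > 0))
})

test_that("computeIndices yields 15 layers, propagates masks, is deterministic", {
  st <- randomBandStack(64L)
  ## mask one pixel in one band -> masked everywhere
  b <- st@bands
  b$B4[1L, 10L] <- NA
  stM <- reflectanceStack(b, month = 7L)
  cube <- computeIndices(stM)
  expect_setequal(names(cube@layers), indexNames())
  for (nm in indexNames())
    expect_true(is.na(indexLayer(cube, nm)[1L, 10L]), label = nm)
  ## mask conservation: no layer has more valid pixels than the input
  nValidIn <- sum(!is.na(stM@bands$B4))
  for (nm in indexNames())
    expect_lte(sum(!is.na(indexLayer(cube, nm))), nValidIn)
  ## determinism
  cube2 <- computeIndices(stM)
  expect_identical(cube@layers, cube2@layers)
  ## uniform stack -> constant layers
  stU <- uniformStack(list(B2 = 0.05, B3 = 0.07, B4 = 0.1, B5 = 0.15,
                           B6 = 0.2, B7 = 0.3, B8 = 0.35, B8A = 0.36))
  cu <- computeIndices(stU)
  for (nm in indexNames())
    expect_equal(sd(indexLayer(cu, nm)), 0, label = nm)
})

test_that("degenerate denominators are masked and errors are named", {
  ## B8 = -B4 impossible physically, but B6 = B5 kills the REIP denominator
  st <- uniformStack(list(B4 = 0.05, B5 = 0.20, B6 = 0.20, B7 = 0.25))
  expect_warning(v <- computeIndex(st, "REIP"), "masked")
  expect_true(all(is.na(v)))

  expect_error(computeIndex(st, "NOPE"), "unknown index")
  expect_error(computeIndex(st, "NDVI"), "B8")

  ## TNDVI masked where NDVI + 0.5 < 0 requires NDVI < -0.5: B8 << B4
  st2 <- reflectanceStack(list(B4 = matrix(0.60, 1L, 2L),
                               B8 = matrix(c(0.10, 0.50), 1L, 2L)),
                          month = 7L)
  v2 <- computeIndex(st2, "TNDVI")
  expect_true(is.na(v2[1L, 1L]))       # NDVI = -0.714
  expect_false(is.na(v2[1L, 2L]))
})

test_that("reflectance validation clamps and masks at construction", {
  b <- list(B4 = matrix(c(-0.005, 0.5, 1.3, 0.2), 2L, 2L),
            B8 = matrix(0.4, 2L, 2L))
  st <- reflectanceStack(b, month = 5L)
  expect_equal(getBand(st, "B4")[1L, 1L], 0)        # clamped from -0.005
  expect_true(is.na(getBand(st, "B4")[1L, 2L]))     # 1.3 out of range
  expect_true(is.na(getBand(st, "B8")[1L, 2L]))     # shared mask
})
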