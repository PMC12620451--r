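## Shared fixtures, generated in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## small clean scene used across module tests
tinyScene <- function() memo("tinyScene",
  generateScene(sceneConfig(nrow = 16L, ncol = 16L, seed = 11L)))

## default-size clean scene for end-to-end checks
defaultScene <- function(seed = 1L) memo(paste0("scene", seed),
  generateScene(sceneConfig(seed = seed)))

## random valid band vectors as a 1 x n stack (for index oracles)
randomBandStack <- function(n, seed = 99L) {
  set.seed(seed)
  bands <- list(
    B2  = runif(n, 0.01, 0.25), B3 = runif(n, 0.02, 0.30),
    B4  = runif(n, 0.02, 0.45), B5 = runif(n, 0.05, 0.45),
    B6  = runif(n, 0.08, 0.50), B7 = runif(n, 0.10, 0.55),
    B8  = runif(n, 0.10, 0.60), B8A = runif(n, 0.10, 0.60)
  )
  reflectanceStack(lapply(bands, function(v) matrix(v, 1L)), month = 7L)
}

## Synthetic index -> FPAR mapping: a latent canopy cover drives all bands
## (so the 15 indices are realistically correlated), and FPAR is a logistic
## function of a weighted sum of normalized indices. Returns the feature
## matrix plus noiseless and noisy targets.
fparMappingData <- function(n = 2756L, noiseSd = 0.02, seed = 7L) {
  key <- sprintf("map_%d_%g_%d", n, noiseSd, seed)
  memo(key, {
    set.seed(seed)
    u <- runif(n)
    canopy <- c(B2 = 0.03, B3 = 0.06, B4 = 0.04, B5 = 0.10, B6 = 0.28,
                B7 = 0.40, B8 = 0.45, B8A = 0.46)
    soil <- c(B2 = 0.10, B3 = 0.14, B4 = 0.20, B5 = 0.22, B6 = 0.25,
              B7 = 0.28, B8 = 0.32, B8A = 0.33)
    bands <- lapply(bandNames(), function(b)
      matrix(u * canopy[[b]] + (1 - u) * soil[[b]] +
               rnorm(n, sd = 0.005), n, 1L))
    names(bands) <- bandNames()
    ft <- cubeToFeatures(computeIndices(reflectanceStack(bands, month = 7L)))
    X <- ft$values
    Z <- apply(X, 2L, function(cc) (cc - min(cc)) / (max(cc) - min(cc)))
    w <- c(ARVI = 0.5, DVI = 1.5, GEMI = 1.0, NDI45 = 0.8, NDVI = 1.2,
           RVI = 0.7, SAVI = 1.3)
    s <- as.numeric(Z[, names(w)] %*% w)
    s <- (s - mean(s)) / sd(s)
    y <- plogis(1.8 * s) * 0.9 + 0.02
    yNoisy <- pmin(pmax(y + rnorm(length(y), sd = noiseSd), 0), 1)
    list(features = featureMatrix(X), y = y, yNoisy = yNoisy)
  })
}

## constant uniform stack builder
uniformStack <- function(vals, nrow = 3L, ncol = 3L, month = 7L) {
  reflectanceStack(lapply(vals, function(v) matrix(v, nrow, ncol)),
                   month = month)
}
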