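#' @include casa.R fpar.R
NULL

.DEFAULT_LAI <- list(
  rice   = list(peak = 4.0, peakMonth = 7.5, width = 2.0, rate = 2.0),
  corn   = list(peak = 4.5, peakMonth = 7.5, width = 2.2, rate = 2.0),
  forest = list(peak = 5.0, peakMonth = 7.0, width = 3.0, rate = 1.5),
  soil   = list(peak = 0.0, peakMonth = 7.0, width = 2.0, rate = 2.0)
)

## Canopy and bare-soil reflectance endmembers per band. The soil values sit
## on the default soil line (NIR = 0.08 + 1.2 x red); canopy values follow a
## green-vegetation spectrum with the red edge between B4 and B7.
.DEFAULT_ENDMEMBERS <- list(
  canopy = c(B2 = 0.03, B3 = 0.06, B4 = 0.04, B5 = 0.10, B6 = 0.28,
             B7 = 0.40, B8 = 0.45, B8A = 0.46),
  soil   = c(B2 = 0.10, B3 = 0.14, B4 = 0.20, B5 = 0.22, B6 = 0.25,
             B7 = 0.28, B8 = 0.32, B8A = 0.33)
)

.DEFAULT_CLOUD_REFL <- c(B2 = 0.45, B3 = 0.43, B4 = 0.42, B5 = 0.41,
                         B6 = 0.40, B7 = 0.40, B8 = 0.39, B8A = 0.39)

#' Synthetic scene configuration
#'
#' Defines a self-contained seasonal crop world: a class layout (rice,
#' corn, forest, bare soil), per-class double-logistic LAI phenology,
#' Beer-Lambert FPAR (extinction k = 0.5), linear canopy/soil spectral
#' mixing with per-band Gaussian noise, sinusoidal monthly meteorology
#' matching the configured annual climate (defaults: 9.3 degC mean
#' temperature, 710.2 mm annual precipitation), and optional cloud patches.
#'
#' @param nrow,ncol grid shape (default 32 x 32).
#' @param cellsize pixel size in map units (default 10).
#' @param classFractions named fractions over rice/corn/forest/soil summing
#'   to 1.
#' @param season growing-season months (default 4:10).
#' @param laiCurves per-class list(peak, peakMonth, width, rate).
#' @param k Beer-Lambert extinction coefficient (default 0.5).
#' @param endmembers list(canopy, soil) of per-band reflectance.
#' @param noiseSigma per-band reflectance noise SD (scalar or named vector,
#'   default 0.01).
#' @param cloudMonths months receiving cloud patches (default none).
#' @param cloudFraction fraction of pixels contaminated in those months.
#' @param cloudReflectance per-band cloud-top reflectance.
#' @param tMean,tAmp annual mean temperature and seasonal half-amplitude
#'   (degC).
#' @param precipAnnual annual precipitation total (mm).
#' @param solMean,solAmp monthly solar radiation mean and half-amplitude
#'   (MJ/m2/month).
#' @param lat site latitude (degrees) for day length.
#' @param epsilonMax maximum light-use efficiency (gC/MJ) used by the truth
#'   forward model.
#' @param seed RNG seed; the whole scene is reproducible from it.
#' @return a validated list of class \code{SceneConfig}.
#' @export
sceneConfig <- function(nrow = 32L, ncol = 32L, cellsize = 10,
                        classFractions = c(rice = 0.35, corn = 0.35,
                                           forest = 0.10, soil = 0.20),
                        season = 4:10, laiCurves = .DEFAULT_LAI, k = 0.5,
                        endmembers = .DEFAULT_ENDMEMBERS, noiseSigma = 0.01,
                        cloudMonths = integer(0), cloudFraction = 0.25,
                        cloudReflectance = .DEFAULT_CLOUD_REFL,
                        tMean = 9.3, tAmp = 15.5, precipAnnual = 710.2,
                        solMean = 420, solAmp = 250, lat = 41,
                        epsilonMax = 0.389, seed = 1L) {
  stopifnot(abs(sum(classFractions) - 1) < 1e-9, k > 0,
            all(noiseSigma >= 0), cloudFraction >= 0, cloudFraction <= 1,
            all(season %in% 1:12))
  if (!all(names(classFractions) %in% names(laiCurves)))
    stop("every layout class needs an LAI curve", call. = FALSE)
  if (length(noiseSigma) == 1L)
    noiseSigma <- setNames(rep(noiseSigma, length(S2_BANDS)), S2_BANDS)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = cellsize, classFractions = classFractions,
                 season = as.integer(season), laiCurves = laiCurves, k = k,
                 endmembers = endmembers, noiseSigma = noiseSigma,
                 cloudMonths = as.integer(cloudMonths),
                 cloudFraction = cloudFraction,
                 cloudReflectance = cloudReflectance, tMean = tMean,
                 tAmp = tAmp, precipAnnual = precipAnnual, solMean = solMean,
                 solAmp = solAmp, lat = lat, epsilonMax = epsilonMax,
                 seed = as.integer(seed)),
            class = "SceneConfig")
}

## double-logistic seasonal curve, normalized so the peak month hits `peak`
.laiAt <- function(month, curve) {
  if (curve$peak <= 0) return(rep(0, length(month)))
  g <- function(t) {
    on <- curve$peakMonth - curve$width
    off <- curve$peakMonth + curve$width
    plogis(curve$rate * (t - on)) * plogis(curve$rate * (off - t))
  }
  curve$peak * g(month) / g(curve$peakMonth)
}

## blocky class layout: contiguous column bands per class, deterministic
.classLayout <- function(cfg) {
  classes <- names(cfg$classFractions)
  npix <- cfg$nrow * cfg$ncol
  counts <- round(cfg$classFractions * npix)
  counts[length(counts)] <- npix - sum(counts[-length(counts)])
  matrix(rep(classes, counts), cfg$nrow, cfg$ncol)
}

.monthTemp <- function(cfg, m) cfg$tMean + cfg$tAmp * cos(2 * pi * (m - 7) / 12)

.monthPrecipWeights <- function() {
  w <- pmax(1 + 1.6 * cos(2 * pi * (1:12 - 7.5) / 12), 0.02)
  w / sum(w)
}

.monthSol <- function(cfg, m)
  pmax(cfg$solMean + cfg$solAmp * cos(2 * pi * (m - 6.5) / 12), 0)

#' Generate a synthetic scene with ground truth
#'
#' Per pixel and month: LAI from the class phenology curve (with a smooth
#' spatial fertility field), FPAR = 1 - exp(-k LAI), fractional cover =
#' FPAR, band reflectance = cover x canopy + (1 - cover) x soil + noise;
#' meteorology follows seasonal sinusoids with mild spatial gradients; true
#' NPP is the CASA forward model run on the true FPAR and scene
#' meteorology. Bit-reproducible from the config seed. When
#' \code{cloudMonths} is set the stacks of those months are contaminated
#' via \code{\link{injectClouds}} (truth is untouched).
#'
#' @param cfg a \code{\link{sceneConfig}}.
#' @return a \linkS4class{SceneTruth}.
#' @export
generateScene <- function(cfg = sceneConfig()) {
  stopifnot(inherits(cfg, "SceneConfig"))
  set.seed(cfg$seed)
  georef <- gridGeoref(cfg$nrow, cfg$ncol, cellsize = cfg$cellsize)
  classMap <- .classLayout(cfg)
  npix <- cfg$nrow * cfg$ncol

  ## smooth fertility field modulating peak LAI by +-15%
  rowf <- matrix(row(classMap) / cfg$nrow, cfg$nrow, cfg$ncol)
  colf <- matrix(col(classMap) / cfg$ncol, cfg$nrow, cfg$ncol)
  fertility <- 1 + 0.15 * sin(2 * pi * rowf + 1) * cos(2 * pi * colf + 2) +
    matrix(rnorm(npix, sd = 0.03), cfg$nrow, cfg$ncol)

  season <- cfg$season
  laiBase <- vapply(season, function(m) {
    base <- matrix(0, cfg$nrow, cfg$ncol)
    for (cl in unique(as.vector(classMap))) {
      sel <- classMap == cl
      base[sel] <- .laiAt(m, cfg$laiCurves[[cl]])
    }
    base
  }, matrix(0, cfg$nrow, cfg$ncol))
  lai <- lapply(seq_along(season),
                function(i) pmax(laiBase[, , i] * fertility, 0))
  names(lai) <- as.character(season)

  fpar <- lapply(lai, function(L) 1 - exp(-cfg$k * L))
  fparFields <- lapply(names(fpar), function(k)
    fparField(fpar[[k]], month = as.integer(k), source = "truth",
              georef = georef))
  names(fparFields) <- names(fpar)

  stacks <- lapply(names(fpar), function(kmon) {
    cover <- fpar[[kmon]]
    bands <- lapply(S2_BANDS, function(b) {
      mu <- cover * cfg$endmembers$canopy[[b]] +
        (1 - cover) * cfg$endmembers$soil[[b]]
      noisy <- mu + matrix(rnorm(npix, sd = cfg$noiseSigma[[b]]),
                           cfg$nrow, cfg$ncol)
      pmax(noisy, 0)
    })
    names(bands) <- S2_BANDS
    reflectanceStack(bands, month = as.integer(kmon), georef = georef)
  })
  names(stacks) <- names(fpar)

  ## meteorology, all 12 months (Thornthwaite needs the annual heat index)
  pw <- .monthPrecipWeights()
  meteo <- lapply(1:12, function(m) {
    tGrad <- 0.5 * (rowf - 0.5)                 # mild N-S gradient, degC
    sGrad <- 5 * (colf - 0.5)                   # MJ gradient
    meteoGrid(sol = pmax(.monthSol(cfg, m) + sGrad, 0),
              temp = .monthTemp(cfg, m) + tGrad,
              precip = pmax(cfg$precipAnnual * pw[m] * (1 + 0.1 * (colf - 0.5)), 0),
              month = m, georef = georef)
  })
  names(meteo) <- as.character(1:12)

  ## Topt: mean temperature of the month of peak greenness (ties earliest)
  topt <- estimateTopt(lai, lapply(meteo[names(lai)], function(m) m@temp))

  npp <- runCasa(fparFields, meteo, topt, epsilonMax = cfg$epsilonMax,
                 season = season, lat = cfg$lat, provenance = "truth")

  cloudMask <- lapply(stacks, function(s)
    matrix(FALSE, cfg$nrow, cfg$ncol))
  names(cloudMask) <- names(stacks)

  truth <- new("SceneTruth", stacks = stacks, fpar = fparFields,
               meteo = meteo, topt = topt, npp = npp,
               cloudMask = cloudMask, classMap = classMap,
               config = unclass(cfg), georef = georef)
  if (length(cfg$cloudMonths))
    truth <- injectClouds(truth, months = cfg$cloudMonths,
                          patchFraction = cfg$cloudFraction,
                          reflectance = cfg$cloudReflectance,
                          seed = cfg$seed + 1000L)
  truth
}

#' Contaminate scene months with cloud patches
#'
#' Random rectangular patches in the configured months are overwritten with
#' bright cloud-top reflectance (high blue) and flagged in the cloud mask.
#' Contamination is observational: the stored true FPAR and NPP are
#' untouched, so recovery errors on cloudy months can be measured against
#' clean truth.
#'
#' @param truth a \linkS4class{SceneTruth}.
#' @param months season months to contaminate.
#' @param patchFraction target fraction of pixels flagged (0..1).
#' @param reflectance named per-band cloud reflectance.
#' @param seed RNG seed for patch placement.
#' @return the modified \linkS4class{SceneTruth}.
#' @export
injectClouds <- function(truth, months, patchFraction = 0.25,
                         reflectance = .DEFAULT_CLOUD_REFL, seed = 1001L) {
  stopifnot(is(truth, "SceneTruth"), patchFraction >= 0, patchFraction <= 1)
  set.seed(seed)
  for (m in as.character(months)) {
    if (!m %in% names(truth@stacks))
      stop("month not present in scene: ", m, call. = FALSE)
    st <- truth@stacks[[m]]
    nr <- nrow(st@bands[[1L]]); nc <- ncol(st@bands[[1L]])
    mask <- matrix(FALSE, nr, nc)
    target <- round(patchFraction * nr * nc)
    guard <- 0L
    while (sum(mask) < target && guard < 1000L) {
      h <- sample.int(max(2L, nr %/% 3L), 1L) + 1L
      w <- sample.int(max(2L, nc %/% 3L), 1L) + 1L
      r0 <- sample.int(nr - h + 1L, 1L)
      c0 <- sample.int(nc - w + 1L, 1L)
      mask[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
      guard <- guard + 1L
    }
    if (patchFraction >= 1) mask[] <- TRUE
    ## trim overshoot so the flagged fraction is close to the target
    if (sum(mask) > target) {
      on <- which(mask)
      mask[sample(on, sum(mask) - target)] <- FALSE
    }
    for (b in names(st@bands)) {
      g <- st@bands[[b]]
      g[mask] <- reflectance[[b]] +
        rnorm(sum(mask), sd = truth@config$noiseSigma[[b]])
      st@bands[[b]] <- g
    }
    truth@stacks[[m]] <- reflectanceStack(st@bands, month = st@month,
                                          georef = st@georef)
    truth@cloudMask[[m]] <- mask
  }
  truth
}

#' Sample a training set from a scene
#'
#' Computes the 15-index cube for each requested month and pairs sampled
#' unmasked pixels with the scene's true FPAR, pooling months evenly --
#' the stand-in for the reference-FPAR labels a real campaign would
#' provide.
#'
#' @param truth a \linkS4class{SceneTruth}.
#' @param nSamples total samples (default 2756).
#' @param months season months to draw from (default: all scene months).
#' @param params \code{\link{indexParams}} for the index computation.
#' @param seed RNG seed for the pixel draw.
#' @return list(features = \code{\link{featureMatrix}}, y = FPAR vector,
#'   month, pixelIndex).
#' @export
buildTrainingSet <- function(truth, nSamples = 2756L, months = NULL,
                             params = indexParams(), seed = 42L) {
  stopifnot(is(truth, "SceneTruth"))
  if (is.null(months)) months <- names(truth@stacks)
  months <- as.character(months)
  set.seed(seed)
  per <- diff(round(seq(0, nSamples, length.out = length(months) + 1L)))
  rows <- list()
  for (i in seq_along(months)) {
    m <- months[i]
    ft <- cubeToFeatures(computeIndices(truth@stacks[[m]], params))
    take <- sample(length(ft$pixelIndex), per[i],
                   replace = per[i] > length(ft$pixelIndex))
    idx <- ft$pixelIndex[take]
    rows[[m]] <- list(x = ft$values[take, , drop = FALSE],
                      y = truth@fpar[[m]]@values[idx],
                      month = rep(as.integer(m), per[i]), idx = idx)
  }
  x <- do.call(rbind, lapply(rows, `[[`, "x"))
  list(features = featureMatrix(x, INDEX_NAMES),
       y = unlist(lapply(rows, `[[`, "y"), use.names = FALSE),
       month = unlist(lapply(rows, `[[`, "month"), use.names = FALSE),
       pixelIndex = unlist(lapply(rows, `[[`, "idx"), use.names = FALSE))
}
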