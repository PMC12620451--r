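#' @include constructors.R
NULL

## days per month, non-leap calendar (monthly climatology convention)
DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

.asGrid <- function(x) {
  if (is(x, "FparField")) return(x@values)
  as.matrix(x)
}

#' Absorbed photosynthetically active radiation
#'
#' APAR = SOL x FPAR x 0.5 (MJ/m2/month): PAR is taken as half the total
#' shortwave solar radiation, and FPAR is the fraction the canopy absorbs.
#'
#' @param sol monthly total solar radiation grid (MJ/m2/month).
#' @param fpar an \linkS4class{FparField} or numeric grid in [0,1].
#' @return APAR grid (MJ/m2/month).
#' @export
computeApar <- function(sol, fpar) {
  sol <- as.matrix(sol); f <- .asGrid(fpar)
  if (!identical(dim(sol), dim(f)))
    stop("SOL and FPAR grids have mismatched shapes: ",
         paste(dim(sol), collapse = "x"), " vs ",
         paste(dim(f), collapse = "x"), call. = FALSE)
  sol * f * 0.5
}

#' Low-temperature stress scalar Te1
#'
#' Quadratic in the optimal temperature Topt (the mean temperature of the
#' peak-greenness month): Te1 = 0.8 + 0.02 Topt - 0.0005 Topt^2, clamped to
#' [0, 1]. In months whose mean temperature is at or below -10 degC the
#' vegetation is dormant and Te1 = 0.
#'
#' @param topt optimal temperature, scalar or grid (degC).
#' @param temp optional monthly mean temperature grid (degC) for the
#'   frozen-month cutoff; omit to skip the cutoff.
#' @return Te1 grid in [0, 1].
#' @export
tempStressLow <- function(topt, temp = NULL) {
  t1 <- 0.8 + 0.02 * topt - 0.0005 * topt^2
  t1 <- pmin(pmax(t1, 0), 1)
  if (!is.null(temp)) {
    temp <- as.matrix(temp)
    if (is.matrix(t1) && !identical(dim(t1), dim(temp)))
      stop("topt and temp grids have mismatched shapes", call. = FALSE)
    if (!is.matrix(t1)) t1 <- matrix(t1, nrow(temp), ncol(temp))
    t1[temp <= -10] <- 0
  }
  t1
}

#' High-temperature stress scalar Te2
#'
#' Double-logistic down-regulation around Topt with the 1.1814 normalizer:
#' Te2 = 1.1814 / ((1 + exp(0.2 (Topt - 10 - T))) (1 + exp(0.3 (-Topt - 10 + T)))),
#' clamped to [0, 1]. At T = Topt the value is ~0.9914; it decays to 0 for
#' temperatures far below Topt - 10 or above Topt + 10.
#'
#' @param temp monthly mean temperature grid (degC).
#' @param topt optimal temperature, scalar or grid (degC).
#' @return Te2 grid in [0, 1].
#' @export
tempStressHigh <- function(temp, topt) {
  temp <- as.matrix(temp)
  t2 <- 1.1814 / ((1 + exp(0.2 * (topt - 10 - temp))) *
                  (1 + exp(0.3 * (-topt - 10 + temp))))
  pmin(pmax(t2, 0), 1)
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' PET_m = 16 (10 T_m / I)^a corrected by mean day length and month length,
#' where I is the annual heat index sum((T_m/5)^1.514) over months with
#' T_m > 0 and a is Thornthwaite's cubic in I. Day length is computed at the
#' site latitude for mid-month. Months at or below 0 degC get PET = 0.
#'
#' @param temp list (or 3-d array) of 12 monthly mean temperature grids
#'   (degC), in month order; a full year is expected so the heat index is
#'   well defined.
#' @param lat site latitude in degrees (scalar), used for the day-length
#'   correction.
#' @return list of 12 PET grids (mm/month).
#' @export
thornthwaitePet <- function(temp, lat = 41) {
  if (is.array(temp) && length(dim(temp)) == 3L)
    temp <- lapply(seq_len(dim(temp)[3L]), function(k) temp[, , k])
  stopifnot(length(temp) == 12L)
  temp <- lapply(temp, as.matrix)
  tPos <- lapply(temp, function(tm) pmax(tm, 0))
  I <- Reduce(`+`, lapply(tPos, function(tm) (tm / 5)^1.514))
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  midDoy <- cumsum(DAYS_IN_MONTH) - DAYS_IN_MONTH / 2
  lapply(seq_len(12L), function(m) {
    dayLen <- geosphere::daylength(lat, midDoy[m])
    pet <- 16 * (10 * tPos[[m]] / I)^a * (dayLen / 12) * (DAYS_IN_MONTH[m] / 30)
    pet[I <= 0] <- 0
    pet[tPos[[m]] <= 0] <- 0
    pet
  })
}

#' Water stress scalar We
#'
#' We = 0.5 + 0.5 EET/PET with the ratio clamped to [0, 1], so We lies in
#' [0.5, 1]. The estimated evapotranspiration defaults to the
#' supply-demand bound EET = min(P, PET); externally computed EET grids
#' (e.g. from a regional evapotranspiration model) can be supplied instead.
#' Where PET = 0 there is no atmospheric demand and We = 1.
#'
#' @param precip monthly precipitation grid (mm), non-negative.
#' @param pet monthly potential evapotranspiration grid (mm).
#' @param eet optional externally supplied actual-evapotranspiration grid
#'   (mm); defaults to min(precip, pet).
#' @return We grid in [0.5, 1].
#' @export
waterStress <- function(precip, pet, eet = NULL) {
  precip <- as.matrix(precip); pet <- as.matrix(pet)
  if (any(precip < 0, na.rm = TRUE))
    stop("negative precipitation is not physical", call. = FALSE)
  if (is.null(eet)) eet <- pmin(precip, pet)
  ratio <- eet / pet
  ratio[pet <= 0] <- 1          # no demand => moisture non-limiting
  ratio <- pmin(pmax(ratio, 0), 1)
  0.5 + 0.5 * ratio
}

#' Actual light-use efficiency
#'
#' epsilon = Te1 x Te2 x We x epsilon_max (gC/MJ); bounded by epsilon_max
#' and zero whenever any stress factor vanishes. The default maximum
#' light-use efficiency for cropland is 0.389 gC/MJ; a per-pixel grid (e.g.
#' from a crop-class lookup) may be passed instead of the scalar.
#'
#' @param te1,te2,we stress scalar grids in [0, 1].
#' @param epsilonMax maximum light-use efficiency, scalar or grid (gC/MJ).
#' @return epsilon grid (gC/MJ).
#' @export
actualLue <- function(te1, te2, we, epsilonMax = 0.389) {
  stopifnot(all(epsilonMax > 0, na.rm = TRUE))
  te1 * te2 * we * epsilonMax
}

#' Monthly NPP
#'
#' NPP = APAR x epsilon, pointwise (gC/m2/month).
#'
#' @param apar APAR grid (MJ/m2/month).
#' @param epsilon actual light-use efficiency grid (gC/MJ).
#' @return NPP grid (gC/m2/month).
#' @export
monthlyNpp <- function(apar, epsilon) {
  apar <- as.matrix(apar)
  out <- apar * epsilon
  out[out < 0] <- 0
  out
}

#' Growing-season NPP aggregation
#'
#' Pointwise sum of the monthly grids over the configured season (default
#' April--October). Under the strict mask policy a pixel masked in any
#' month is masked in the seasonal total; under "partial" the available
#' months are summed.
#'
#' @param monthly named list of monthly NPP grids; names are month numbers.
#' @param season integer months that must be present (default 4:10).
#' @param policy "strict" (default) or "partial".
#' @return seasonal NPP grid (gC/m2).
#' @export
seasonNpp <- function(monthly, season = 4:10, policy = c("strict", "partial")) {
  policy <- match.arg(policy)
  missing <- setdiff(as.character(season), names(monthly))
  if (length(missing))
    stop("missing month(s) for season sum: ", paste(missing, collapse = ", "),
         call. = FALSE)
  grids <- lapply(monthly[as.character(season)], as.matrix)
  if (policy == "strict") {
    Reduce(`+`, grids)
  } else {
    tot <- Reduce(`+`, lapply(grids, function(g) { g[is.na(g)] <- 0; g }))
    allNA <- Reduce(`&`, lapply(grids, is.na))
    tot[allNA] <- NA_real_
    tot
  }
}

#' Optimal temperature from NDVI and temperature time series
#'
#' Topt at each pixel is the mean temperature of the month in which NDVI
#' attains its seasonal maximum; ties break toward the earlier month.
#'
#' @param ndvi named list of monthly NDVI grids (names = month numbers,
#'   ascending).
#' @param temp named list of monthly mean temperature grids over the same
#'   months.
#' @return Topt grid (degC).
#' @export
estimateTopt <- function(ndvi, temp) {
  stopifnot(length(ndvi) >= 1L, identical(names(ndvi), names(temp)))
  nm <- length(ndvi)
  npix <- length(ndvi[[1L]])
  ndviMat <- matrix(unlist(lapply(ndvi, as.vector)), npix, nm)
  tempMat <- matrix(unlist(lapply(temp, as.vector)), npix, nm)
  if (nm == 1L) {
    best <- rep(1L, npix)
  } else {
    best <- max.col(ndviMat, ties.method = "first")
  }
  out <- tempMat[cbind(seq_len(nrow(tempMat)), best)]
  matrix(out, nrow(ndvi[[1L]]), ncol(ndvi[[1L]]))
}

#' Run the CASA model over a season
#'
#' Chains APAR, the temperature and water stress scalars and the monthly
#' NPP product over the configured growing season, then aggregates.
#' Thornthwaite PET is derived from the full-year monthly temperature
#' grids unless EET/PET grids are supplied.
#'
#' @param fpar named list of \linkS4class{FparField} (or grids), one per
#'   season month.
#' @param meteo named list of \linkS4class{MeteoGrid} covering at least the
#'   season; all 12 months are expected for the Thornthwaite heat index
#'   (missing months are treated as the coldest-month default of 0 degC
#'   with a warning).
#' @param topt optimal temperature grid or scalar (degC).
#' @param epsilonMax maximum light-use efficiency (gC/MJ), scalar or grid.
#' @param season integer months (default 4:10, April--October).
#' @param lat site latitude for day length (default 41).
#' @param pet optional named list of PET grids (mm) to use instead of
#'   Thornthwaite; \code{eet} likewise overrides min(P, PET).
#' @param eet optional named list of EET grids (mm).
#' @param policy mask policy for the seasonal sum.
#' @param provenance provenance string recorded on the result.
#' @return an \linkS4class{NppGrid}.
#' @export
runCasa <- function(fpar, meteo, topt, epsilonMax = 0.389, season = 4:10,
                    lat = 41, pet = NULL, eet = NULL,
                    policy = c("strict", "partial"), provenance = "cnn") {
  policy <- match.arg(policy)
  season <- as.integer(season)
  keys <- as.character(season)
  missF <- setdiff(keys, names(fpar))
  if (length(missF))
    stop("missing FPAR month(s): ", paste(missF, collapse = ", "),
         call. = FALSE)
  missM <- setdiff(keys, names(meteo))
  if (length(missM))
    stop("missing meteorology month(s): ", paste(missM, collapse = ", "),
         call. = FALSE)

  georef <- if (is(meteo[[keys[1L]]], "MeteoGrid"))
    meteo[[keys[1L]]]@georef else NULL

  if (is.null(pet)) {
    shape <- dim(if (is(meteo[[keys[1L]]], "MeteoGrid"))
      meteo[[keys[1L]]]@temp else as.matrix(meteo[[keys[1L]]]$temp))
    tempYear <- lapply(as.character(1:12), function(k) {
      if (k %in% names(meteo)) {
        m <- meteo[[k]]
        if (is(m, "MeteoGrid")) m@temp else as.matrix(m$temp)
      } else {
        warning("month ", k, " missing from meteorology; ",
                "using 0 degC for the Thornthwaite heat index",
                call. = FALSE)
        matrix(0, shape[1L], shape[2L])
      }
    })
    pet <- thornthwaitePet(tempYear, lat = lat)
    names(pet) <- as.character(1:12)
  }

  monthly <- list()
  for (k in keys) {
    m <- meteo[[k]]
    sol <- if (is(m, "MeteoGrid")) m@sol else as.matrix(m$sol)
    temp <- if (is(m, "MeteoGrid")) m@temp else as.matrix(m$temp)
    prec <- if (is(m, "MeteoGrid")) m@precip else as.matrix(m$precip)
    apar <- computeApar(sol, fpar[[k]])
    te1 <- tempStressLow(topt, temp)
    te2 <- tempStressHigh(temp, topt)
    we <- waterStress(prec, pet[[k]],
                      eet = if (!is.null(eet)) eet[[k]] else NULL)
    epsilon <- actualLue(te1, te2, we, epsilonMax)
    monthly[[k]] <- monthlyNpp(apar, epsilon)
  }
  annual <- seasonNpp(monthly, season = season, policy = policy)
  if (is.null(georef)) georef <- gridGeoref(nrow(annual), ncol(annual))
  new("NppGrid", monthly = monthly, annual = annual, season = season,
      provenance = provenance, georef = georef)
}
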