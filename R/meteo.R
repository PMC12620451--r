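#' @include constructors.R
NULL

#' Convert daily radiation to a monthly total
#'
#' Station solar radiation often arrives as J/m2/day; the model wants
#' MJ/m2/month: value x days-in-month / 1e6. A non-leap calendar is used.
#'
#' @param daily radiation in J/m2/day (vector ok).
#' @param month month number 1--12 (recycled against \code{daily}).
#' @return MJ/m2/month.
#' @examples
#' convertRadiation(1e6, 6)   # 30 MJ/m2/month
#' @export
convertRadiation <- function(daily, month) {
  stopifnot(all(month %in% 1:12))
  daily * DAYS_IN_MONTH[month] / 1e6
}

## Empirical semivariogram: average of 0.5*(z_i - z_j)^2 in distance bins.
.empiricalVariogram <- function(x, y, z, nbins = 8) {
  d <- as.matrix(dist(cbind(x, y)))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  h <- d[iu]
  g <- 0.5 * (z[iu[, 1L]] - z[iu[, 2L]])^2
  breaks <- seq(0, max(h), length.out = nbins + 1L)
  bin <- cut(h, breaks, include.lowest = TRUE)
  keep <- tapply(g, bin, length)
  data.frame(h = tapply(h, bin, mean)[!is.na(keep)],
             gamma = tapply(g, bin, mean)[!is.na(keep)],
             npairs = keep[!is.na(keep)])
}

#' Fit an exponential variogram by weighted least squares
#'
#' gamma(h) = nugget + psill (1 - exp(-h / range)), fitted to the binned
#' empirical semivariogram with npairs/h^2 weights (close, well-populated
#' bins dominate). The nugget may be fixed (default 0, which makes kriging
#' exact at the stations).
#'
#' @param x,y station coordinates.
#' @param z station values.
#' @param nugget fixed nugget, or NA to estimate it.
#' @param nbins number of distance bins.
#' @return list(nugget, psill, range, empirical).
#' @export
fitVariogram <- function(x, y, z, nugget = 0, nbins = 8) {
  emp <- .empiricalVariogram(x, y, z, nbins = nbins)
  w <- emp$npairs / pmax(emp$h, min(emp$h))^2
  s2 <- max(var(z), 1e-12)
  maxh <- max(emp$h)
  ## range is clamped: trend-like (unbounded) semivariograms otherwise push
  ## it to infinity and the kriging system toward singularity
  clampRange <- function(r) min(max(r, maxh / 50), 3 * maxh)
  obj <- function(p) {
    psill <- exp(p[1L]); rng <- clampRange(exp(p[2L]))
    ng <- if (is.na(nugget)) exp(p[3L]) else nugget
    fit <- ng + psill * (1 - exp(-emp$h / rng))
    sum(w * (fit - emp$gamma)^2)
  }
  init <- c(log(s2), log(maxh / 3),
            if (is.na(nugget)) log(s2 / 10) else NULL)
  opt <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 500))
  list(nugget = if (is.na(nugget)) exp(opt$par[3L]) else nugget,
       psill = exp(opt$par[1L]), range = clampRange(exp(opt$par[2L])),
       empirical = emp)
}

.expCov <- function(h, vg) vg$psill * exp(-h / vg$range)

## Ordinary kriging: solve the (n+1) system once, predict all grid nodes.
.krige <- function(sx, sy, z, px, py, vg) {
  n <- length(z)
  d <- as.matrix(dist(cbind(sx, sy)))
  C <- .expCov(d, vg)
  ## tiny jitter keeps near-flat covariances numerically solvable while
  ## preserving station exactness far beyond reporting precision
  diag(C) <- (vg$psill + vg$nugget) * (1 + 1e-9)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(px, sx, "-")^2 + outer(py, sy, "-")^2)
  B <- rbind(t(.expCov(d0, vg)), 1)
  lambda <- solve(A, B)             # (n+1) x npred weights
  drop(crossprod(lambda[seq_len(n), , drop = FALSE], z))
}

.idw <- function(sx, sy, z, px, py, power = 2) {
  d2 <- outer(px, sx, "-")^2 + outer(py, sy, "-")^2
  w <- 1 / pmax(d2, 1e-300)^(power / 2)
  out <- as.vector((w %*% z) / rowSums(w))
  hit <- which(d2 < 1e-18, arr.ind = TRUE)   # exact at coincident nodes
  if (nrow(hit)) out[hit[, 1L]] <- z[hit[, 2L]]
  out
}

#' Interpolate station records to a monthly grid
#'
#' Ordinary kriging with a WLS-fitted exponential variogram (nugget 0 by
#' default, hence exact at station cells), or inverse-distance weighting.
#' A singular or near-singular kriging system falls back to IDW with a
#' warning; fewer than 3 stations always use IDW (a single station gives a
#' constant field).
#'
#' @param stations data.frame with columns \code{lon}, \code{lat} (or
#'   \code{x}, \code{y}) and the value column named by \code{variable}.
#' @param variable name of the value column.
#' @param georef target grid from \code{\link{gridGeoref}} (station
#'   coordinates must be in the same map units).
#' @param method "kriging" or "idw".
#' @param variogram optional list(nugget, psill, range) overriding the fit.
#' @param idwPower IDW power (default 2).
#' @return numeric matrix on the target grid.
#' @export
interpolateGrid <- function(stations, variable, georef,
                            method = c("kriging", "idw"),
                            variogram = NULL, idwPower = 2) {
  method <- match.arg(method)
  cx <- if ("lon" %in% names(stations)) "lon" else "x"
  cy <- if ("lat" %in% names(stations)) "lat" else "y"
  stopifnot(variable %in% names(stations))
  sx <- stations[[cx]]; sy <- stations[[cy]]; z <- stations[[variable]]
  keep <- !(is.na(sx) | is.na(sy) | is.na(z))
  sx <- sx[keep]; sy <- sy[keep]; z <- z[keep]
  if (length(z) < 1L) stop("no usable stations", call. = FALSE)
  if (method == "kriging" && length(z) < 3L)
    stop("kriging needs at least 3 stations; use method = \"idw\"",
         call. = FALSE)

  ## cell-center coordinates, row 1 = top of map
  xs <- georef$xll + (seq_len(georef$ncol) - 0.5) * georef$cellsize
  ys <- georef$yll + (rev(seq_len(georef$nrow)) - 0.5) * georef$cellsize
  px <- rep(xs, each = georef$nrow)
  py <- rep(ys, times = georef$ncol)

  vals <- if (method == "kriging") {
    vg <- if (is.null(variogram)) {
      if (var(z) < 1e-15) list(nugget = 0, psill = 1, range = 1)
      else fitVariogram(sx, sy, z)
    } else variogram
    out <- tryCatch(.krige(sx, sy, z, px, py, vg),
                    error = function(e) {
                      warning("singular kriging system; falling back to IDW",
                              call. = FALSE)
                      .idw(sx, sy, z, px, py, idwPower)
                    })
    if (any(!is.finite(out))) {
      warning("non-finite kriging solution; falling back to IDW",
              call. = FALSE)
      out <- .idw(sx, sy, z, px, py, idwPower)
    }
    out
  } else {
    .idw(sx, sy, z, px, py, idwPower)
  }
  matrix(vals, georef$nrow, georef$ncol)
}

#' Station CSV to monthly MeteoGrid list
#'
#' Reads a station table (station_id, lon, lat, month, sol, temp, precip;
#' \code{sol_daily} in J/m2/day is converted via
#' \code{\link{convertRadiation}} when a monthly \code{sol} column is
#' absent) and interpolates each variable for each month present.
#'
#' @param stations data.frame or path to a CSV.
#' @param georef target grid.
#' @param method interpolation method, see \code{\link{interpolateGrid}}.
#' @return named list of \linkS4class{MeteoGrid} by month.
#' @export
stationsToMeteo <- function(stations, georef, method = "idw") {
  if (is.character(stations)) stations <- read.csv(stations)
  need <- c("lon", "lat", "month", "temp", "precip")
  missing <- setdiff(need, names(stations))
  if (length(missing))
    stop("station table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"sol" %in% names(stations)) {
    if (!"sol_daily" %in% names(stations))
      stop("station table needs a sol (MJ/m2/month) or sol_daily (J/m2/day) column",
           call. = FALSE)
    stations$sol <- convertRadiation(stations$sol_daily, stations$month)
  }
  months <- sort(unique(stations$month))
  out <- lapply(months, function(m) {
    sub <- stations[stations$month == m, , drop = FALSE]
    meteoGrid(sol = interpolateGrid(sub, "sol", georef, method),
              temp = interpolateGrid(sub, "temp", georef, method),
              precip = interpolateGrid(sub, "precip", georef, method),
              month = m, georef = georef)
  })
  names(out) <- as.character(months)
  out
}
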