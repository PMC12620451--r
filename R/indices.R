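#' @include constructors.R
NULL

## Bands each index reads; used for missing-band diagnostics.
.INDEX_BANDS <- list(
  ARVI  = c("B2", "B4", "B8"),
  DVI   = c("B4", "B8"),
  EVI   = c("B2", "B4", "B8"),
  GEMI  = c("B4", "B8A"),
  GNDVI = c("B3", "B7"),
  MSAVI = c("B4", "B8"),
  NDI45 = c("B4", "B5"),
  NDVI  = c("B4", "B8"),
  PVI   = c("B4", "B8"),
  RVI   = c("B4", "B8"),
  REIP  = c("B4", "B5", "B6", "B7"),
  SAVI  = c("B4", "B8"),
  TNDVI = c("B4", "B8"),
  TSAVI = c("B4", "B8"),
  WDVI  = c("B4", "B8")
)

#' Soil-line and calibration constants for the vegetation indices
#'
#' The soil line is the empirical linear relation between bare-soil NIR and
#' red reflectance, NIR = intercept + slope * red; the soil-adjusted indices
#' (PVI, TSAVI, WDVI) read its slope and intercept, TSAVI additionally uses
#' a soil-noise factor X, and SAVI a canopy calibration factor L. Defaults
#' are the standard published values; all are overridable.
#'
#' @param soil_intercept soil-line intercept a (dimensionless, default 0.08).
#' @param soil_slope soil-line slope s (dimensionless, default 1.2); also the
#'   multiplier of the red band in WDVI and TSAVI's s.
#' @param soil_noise TSAVI soil-noise reduction factor X (default 0.08).
#' @param savi_L SAVI canopy background calibration factor L (default 0.5);
#'   L = 0 reduces SAVI to NDVI.
#' @return a validated parameter list of class \code{IndexParams}.
#' @export
indexParams <- function(soil_intercept = 0.08, soil_slope = 1.2,
                        soil_noise = 0.08, savi_L = 0.5) {
  stopifnot(soil_slope > 0, savi_L >= 0, soil_noise >= 0)
  structure(list(soil_intercept = soil_intercept, soil_slope = soil_slope,
                 soil_noise = soil_noise, savi_L = savi_L),
            class = "IndexParams")
}

## Guarded division: |denominator| below tol yields NA (masked), never Inf.
.safeDiv <- function(num, den, tol = 1e-9) {
  out <- num / den
  out[abs(den) < tol] <- NA_real_
  out
}

.indexFormula <- function(name, b, p) {
  a <- p$soil_intercept; s <- p$soil_slope; X <- p$soil_noise; L <- p$savi_L
  switch(name,
    ARVI  = {                       # atmospheric red correction with gamma = 1
      rb <- 2 * b$B4 - b$B2
      .safeDiv(b$B8 - rb, b$B8 + rb)
    },
    DVI   = b$B8 - b$B4,
    EVI   = .safeDiv(2.5 * (b$B8 - b$B4), b$B8 + 6 * b$B4 - 7.5 * b$B2 + 1),
    GEMI  = {
      n <- .safeDiv(2 * (b$B8A^2 - b$B4^2) + 1.5 * b$B8A + 0.5 * b$B4,
                    b$B8A + b$B4 + 0.5)
      n * (1 - 0.25 * n) - .safeDiv(b$B4 - 0.125, 1 - b$B4)
    },
    GNDVI = .safeDiv(b$B7 - b$B3, b$B7 + b$B3),
    MSAVI = {
      rad <- (2 * b$B8 + 1)^2 - 8 * (b$B8 - b$B4)
      rad[rad < 0] <- NA_real_     # complex root => masked, not NaN
      (2 * b$B8 + 1 - sqrt(rad)) / 2
    },
    NDI45 = .safeDiv(b$B5 - b$B4, b$B5 + b$B4),
    NDVI  = .safeDiv(b$B8 - b$B4, b$B8 + b$B4),
    PVI   = (b$B8 - s * b$B4 - a) / sqrt(s^2 + 1),
    RVI   = .safeDiv(b$B8, b$B4),
    REIP  = 705 + 35 * .safeDiv((b$B4 + b$B7) / 2 - b$B5, b$B6 - b$B5),
    SAVI  = (1 + L) * .safeDiv(b$B8 - b$B4, b$B8 + b$B4 + L),
    TNDVI = {
      rad <- .safeDiv(b$B8 - b$B4, b$B8 + b$B4) + 0.5
      rad[rad < 0] <- NA_real_     # real-valued only where NDVI + 0.5 >= 0
      sqrt(rad)
    },
    TSAVI = .safeDiv(s * (b$B8 - s * b$B4 - a),
                     a * b$B8 + b$B4 - a * s + X * (1 + s^2)),
    WDVI  = b$B8 - s * b$B4,
    stop("unknown index name: ", name, call. = FALSE)
  )
}

#' Compute one vegetation index from a reflectance stack
#'
#' Evaluates the per-pixel formula for one of the 15 supported indices.
#' The normalized-difference family (NDVI, GNDVI, NDI45) is bounded in
#' [-1, 1]; ratio and soil-line indices are unbounded. Pixels whose
#' denominator is within 1e-9 of zero, or where a radicand would be
#' negative (MSAVI, TNDVI), are masked (NA) rather than set to infinities.
#'
#' @param stack a \linkS4class{ReflectanceStack}.
#' @param name one of \code{indexNames()}.
#' @param params an \code{\link{indexParams}} list.
#' @return numeric matrix of index values (NA = masked).
#' @examples
#' b <- matrix(0.4, 2, 2)
#' st <- reflectanceStack(list(B4 = matrix(0.08, 2, 2), B8 = b), month = 7)
#' computeIndex(st, "NDVI")  # (0.40 - 0.08) / (0.40 + 0.08)
#' @export
computeIndex <- function(stack, name, params = indexParams()) {
  stopifnot(is(stack, "ReflectanceStack"))
  if (!name %in% INDEX_NAMES)
    stop("unknown index name: ", name, call. = FALSE)
  need <- .INDEX_BANDS[[name]]
  missing <- setdiff(need, names(stack@bands))
  if (length(missing))
    stop("index ", name, " needs missing band(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- .indexFormula(name, stack@bands, params)
  if (all(is.na(out)))
    warning("index ", name, ": all output pixels are masked", call. = FALSE)
  out
}

#' Compute all 15 vegetation indices as an IndexCube
#'
#' Deterministic given the stack and parameters; the input nodata mask is
#' propagated to every layer, and any formula-level masking (degenerate
#' denominators, negative radicands) only removes further pixels.
#'
#' @inheritParams computeIndex
#' @return an \linkS4class{IndexCube}.
#' @export
computeIndices <- function(stack, params = indexParams()) {
  stopifnot(is(stack, "ReflectanceStack"))
  layers <- lapply(INDEX_NAMES, function(nm) computeIndex(stack, nm, params))
  names(layers) <- INDEX_NAMES
  new("IndexCube", layers = layers, month = stack@month,
      georef = stack@georef)
}

#' Flatten an IndexCube to a per-pixel feature matrix
#'
#' Rows are unmasked pixels (masked in no layer), columns the 15 indices in
#' canonical order; pixel linear indices (column-major) are kept so grids
#' can be reassembled after prediction.
#'
#' @param cube an \linkS4class{IndexCube}.
#' @param features optional subset of index names to keep (canonical order
#'   is preserved).
#' @return list with \code{values} (matrix), \code{featureNames},
#'   \code{pixelIndex}, \code{dim}.
#' @export
cubeToFeatures <- function(cube, features = NULL) {
  stopifnot(is(cube, "IndexCube"))
  if (is.null(features)) features <- INDEX_NAMES
  stopifnot(all(features %in% INDEX_NAMES))
  features <- INDEX_NAMES[INDEX_NAMES %in% features]
  mat <- vapply(cube@layers[features], as.vector,
                numeric(length(cube@layers[[1L]])))
  keep <- which(rowSums(is.na(mat)) == 0L)
  list(values = mat[keep, , drop = FALSE], featureNames = features,
       pixelIndex = keep, dim = dim(cube@layers[[1L]]))
}
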