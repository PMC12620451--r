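#' @include AllClasses.R
NULL

#' Georeference descriptor for a pixel-area grid
#'
#' Rasters use the (row, col) convention with row 1 at the map top; the
#' affine placement is the lower-left corner plus a square cell size, which
#' is what the ASCII-grid interchange format records.
#'
#' @param nrow,ncol grid shape.
#' @param xll,yll map coordinates of the lower-left corner.
#' @param cellsize square pixel size in map units.
#' @param crs coordinate reference system identifier (free-form string).
#' @return a georeference list.
#' @export
gridGeoref <- function(nrow, ncol, xll = 0, yll = 0, cellsize = 10,
                       crs = "EPSG:32651") {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  list(nrow = as.integer(nrow), ncol = as.integer(ncol),
       xll = xll, yll = yll, cellsize = cellsize, crs = crs)
}

#' Build a ReflectanceStack with range validation
#'
#' Reflectance marginally below zero (down to -0.01, common after
#' atmospheric correction) is clamped to 0; values outside [-0.01, 1.2] are
#' physically implausible and masked. Masking any band masks the pixel in
#' all bands, so downstream statistics see a single nodata mask.
#'
#' @param bands named list of numeric matrices (names among B2..B8A).
#' @param month acquisition month, 1--12.
#' @param georef georeference from \code{\link{gridGeoref}}; defaulted from
#'   the grid shape when omitted.
#' @return a \linkS4class{ReflectanceStack}.
#' @export
reflectanceStack <- function(bands, month, georef = NULL) {
  stopifnot(is.list(bands), length(bands) >= 1L)
  bands <- lapply(bands, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b[b > -0.01 & b < 0] <- 0
    b[b < -0.01 | b > 1.2] <- NA_real_
    b
  })
  ## one shared nodata mask across bands
  bad <- Reduce(`|`, lapply(bands, is.na))
  bands <- lapply(bands, function(b) { b[bad] <- NA_real_; b })
  if (is.null(georef))
    georef <- gridGeoref(nrow(bands[[1L]]), ncol(bands[[1L]]))
  new("ReflectanceStack", bands = bands, month = as.integer(month),
      georef = georef)
}

#' @rdname reflectanceStack
#' @param x a ReflectanceStack.
#' @param name band name, e.g. "B8".
#' @export
getBand <- function(x, name) {
  stopifnot(is(x, "ReflectanceStack"))
  if (!name %in% names(x@bands))
    stop("band not present in stack: ", name, call. = FALSE)
  x@bands[[name]]
}

#' The 15 vegetation index names in canonical order
#' @return character vector of length 15.
#' @export
indexNames <- function() INDEX_NAMES

#' Sentinel-2 band names the package expects
#' @return character vector of length 8.
#' @export
bandNames <- function() S2_BANDS

#' Extract one index layer from an IndexCube
#' @param x an \linkS4class{IndexCube}.
#' @param name index name, e.g. "NDVI".
#' @export
indexLayer <- function(x, name) {
  stopifnot(is(x, "IndexCube"))
  if (!name %in% names(x@layers))
    stop("unknown index name: ", name, call. = FALSE)
  x@layers[[name]]
}

#' Construct an FparField
#' @param values numeric matrix in [0,1] (NA = masked).
#' @param month integer month.
#' @param source provenance string.
#' @param georef georeference list.
#' @export
fparField <- function(values, month, source = "truth", georef = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(georef)) georef <- gridGeoref(nrow(values), ncol(values))
  new("FparField", values = values, month = as.integer(month),
      source = source, georef = georef)
}

#' @rdname fparField
#' @param x an FparField.
#' @export
fparValues <- function(x) { stopifnot(is(x, "FparField")); x@values }

#' Construct a MeteoGrid
#' @param sol monthly solar radiation grid (MJ/m2/month).
#' @param temp monthly mean temperature grid (degC).
#' @param precip monthly precipitation grid (mm).
#' @param month integer month.
#' @param georef georeference list.
#' @export
meteoGrid <- function(sol, temp, precip, month, georef = NULL) {
  sol <- as.matrix(sol); temp <- as.matrix(temp); precip <- as.matrix(precip)
  if (is.null(georef)) georef <- gridGeoref(nrow(sol), ncol(sol))
  new("MeteoGrid", sol = sol, temp = temp, precip = precip,
      month = as.integer(month), georef = georef)
}

#' Accessors for NppGrid
#' @param x an \linkS4class{NppGrid}.
#' @param month month number (integer) for the monthly layer.
#' @export
nppAnnual <- function(x) { stopifnot(is(x, "NppGrid")); x@annual }

#' @rdname nppAnnual
#' @export
nppMonthly <- function(x, month) {
  stopifnot(is(x, "NppGrid"))
  key <- as.character(month)
  if (!key %in% names(x@monthly))
    stop("month not present in NppGrid: ", month, call. = FALSE)
  x@monthly[[key]]
}

#' Accessors for SceneTruth components
#' @param x a \linkS4class{SceneTruth}.
#' @param month season month number.
#' @export
sceneStack <- function(x, month) {
  stopifnot(is(x, "SceneTruth"))
  x@stacks[[as.character(month)]]
}

#' @rdname sceneStack
#' @export
sceneFpar <- function(x, month) {
  stopifnot(is(x, "SceneTruth"))
  x@fpar[[as.character(month)]]
}

#' @rdname sceneStack
#' @export
sceneMeteo <- function(x, month) {
  stopifnot(is(x, "SceneTruth"))
  x@meteo[[as.character(month)]]
}

#' @rdname sceneStack
#' @export
sceneNpp <- function(x) { stopifnot(is(x, "SceneTruth")); x@npp }

#' @rdname sceneStack
#' @export
sceneTopt <- function(x) { stopifnot(is(x, "SceneTruth")); x@topt }

#' @rdname sceneStack
#' @export
sceneCloudMask <- function(x, month) {
  stopifnot(is(x, "SceneTruth"))
  x@cloudMask[[as.character(month)]]
}

#' @rdname sceneStack
#' @export
sceneClassMap <- function(x) { stopifnot(is(x, "SceneTruth")); x@classMap }

#' Turn an EvalReport into a named list (e.g. for JSON serialization)
#' @param x an \linkS4class{EvalReport}.
#' @export
reportAsList <- function(x) {
  stopifnot(is(x, "EvalReport"))
  list(r2 = x@r2, evs = x@evs, mse = x@mse, rmse = x@rmse, mae = x@mae,
       mape = x@mape, n = x@n, flags = x@flags)
}
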