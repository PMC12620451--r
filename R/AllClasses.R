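#' @include cropCASA-package.R
NULL

## Sentinel-2 band names used throughout; all grids in a stack share one
## resolution (inputs are assumed analysis-ready).
S2_BANDS <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A")

## The 15 vegetation indices, alphabetical (the canonical layer order).
INDEX_NAMES <- c("ARVI", "DVI", "EVI", "GEMI", "GNDVI", "MSAVI", "NDI45",
                 "NDVI", "PVI", "RVI", "REIP", "SAVI", "TNDVI", "TSAVI",
                 "WDVI")

.checkGridList <- function(grids, georef) {
  if (length(grids) == 0L) return("no grids")
  dims <- vapply(grids, function(g) paste(dim(g), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    return("all grids must share an identical shape")
  if (!is.null(georef$nrow) &&
      !identical(dim(grids[[1L]]), c(georef$nrow, georef$ncol)))
    return("grid shape disagrees with georeference")
  TRUE
}

#' ReflectanceStack: multiband surface reflectance on a common grid
#'
#' Per-pixel surface reflectance for Sentinel-2-style bands B2--B8A, all at
#' one spatial resolution, with a shared georeference and an implicit nodata
#' mask (masked pixels are \code{NA} in every band). Reflectance is
#' dimensionless; values are validated to the physically plausible range at
#' construction (see \code{\link{reflectanceStack}}).
#'
#' @slot bands named list of numeric matrices, names among B2..B8A.
#' @slot month integer acquisition month (1--12).
#' @slot georef list with \code{xll}, \code{yll}, \code{cellsize},
#'   \code{nrow}, \code{ncol}, \code{crs}.
#' @exportClass ReflectanceStack
setClass("ReflectanceStack",
         representation(bands = "list", month = "integer", georef = "list"),
         validity = function(object) {
           if (!all(names(object@bands) %in% S2_BANDS))
             return(paste("unknown band names:",
                          paste(setdiff(names(object@bands), S2_BANDS),
                                collapse = ", ")))
           if (length(object@month) != 1L ||
               is.na(object@month) || object@month < 1L || object@month > 12L)
             return("month must be a single integer in 1..12")
           .checkGridList(object@bands, object@georef)
         })

#' IndexCube: the 15 vegetation index layers of one stack
#'
#' @slot layers named list of numeric matrices, one per index, in the
#'   canonical alphabetical order of \code{indexNames()}.
#' @slot month integer acquisition month inherited from the source stack.
#' @slot georef shared georeference list.
#' @exportClass IndexCube
setClass("IndexCube",
         representation(layers = "list", month = "integer", georef = "list"),
         validity = function(object) {
           if (!identical(sort(names(object@layers)), sort(INDEX_NAMES)))
             return("an IndexCube must hold exactly the 15 named index layers")
           .checkGridList(object@layers, object@georef)
         })

#' FparField: fraction of absorbed PAR on a grid
#'
#' FPAR is dimensionless in [0, 1]; masked pixels are \code{NA}.
#'
#' @slot values numeric matrix in [0,1] (or NA).
#' @slot month integer month.
#' @slot source character: which retrieval produced it
#'   ("cnn", "gbdt", "xgb", "empirical", "truth").
#' @slot georef georeference list.
#' @exportClass FparField
setClass("FparField",
         representation(values = "matrix", month = "integer",
                        source = "character", georef = "list"),
         validity = function(object) {
           v <- object@values
           if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
             return("FPAR values must lie in [0, 1]")
           TRUE
         })

#' MeteoGrid: model-ready monthly meteorology on the analysis grid
#'
#' @slot sol monthly total solar radiation (MJ/m2/month), non-negative.
#' @slot temp monthly mean air temperature (degC).
#' @slot precip monthly precipitation (mm/month), non-negative.
#' @slot month integer month 1--12.
#' @slot georef georeference list.
#' @exportClass MeteoGrid
setClass("MeteoGrid",
         representation(sol = "matrix", temp = "matrix", precip = "matrix",
                        month = "integer", georef = "list"),
         validity = function(object) {
           if (any(object@sol < 0, na.rm = TRUE))
             return("solar radiation must be non-negative")
           if (any(object@precip < 0, na.rm = TRUE))
             return("precipitation must be non-negative")
           .checkGridList(list(object@sol, object@temp, object@precip),
                          object@georef)
         })

#' NppGrid: monthly and growing-season net primary productivity
#'
#' @slot monthly named list of matrices (gC/m2/month), names are month numbers.
#' @slot annual matrix, growing-season sum (gC/m2/season-year).
#' @slot season integer vector of months summed into \code{annual}.
#' @slot provenance character: FPAR source that produced it.
#' @slot georef georeference list.
#' @exportClass NppGrid
setClass("NppGrid",
         representation(monthly = "list", annual = "matrix",
                        season = "integer", provenance = "character",
                        georef = "list"),
         validity = function(object) {
           if (any(unlist(object@monthly) < -1e-9, na.rm = TRUE))
             return("monthly NPP must be non-negative on valid pixels")
           .checkGridList(c(object@monthly, list(object@annual)),
                          object@georef)
         })

#' SceneTruth: a fully simulated test world with ground truth
#'
#' Everything the pipeline consumes plus the true FPAR/NPP it should
#' recover: monthly reflectance stacks, monthly meteorology (all 12 months,
#' so Thornthwaite's annual heat index is well defined), the optimal
#' temperature grid, cloud flags, and the stored forward-model NPP.
#'
#' @slot stacks named list of \linkS4class{ReflectanceStack}, one per season month.
#' @slot fpar named list of true \linkS4class{FparField} per season month.
#' @slot meteo named list of \linkS4class{MeteoGrid}, months "1".."12".
#' @slot topt matrix of optimal temperature (degC).
#' @slot npp \linkS4class{NppGrid} of true NPP (provenance "truth").
#' @slot cloudMask named list of logical matrices per season month
#'   (TRUE = cloud-contaminated observation; truth is untouched).
#' @slot classMap character matrix of surface classes (rice/corn/forest/soil).
#' @slot config the \code{\link{sceneConfig}} that produced the scene.
#' @slot georef georeference list.
#' @exportClass SceneTruth
setClass("SceneTruth",
         representation(stacks = "list", fpar = "list", meteo = "list",
                        topt = "matrix", npp = "NppGrid", cloudMask = "list",
                        classMap = "matrix", config = "list", georef = "list"))

#' EvalReport: the evaluation metric suite
#'
#' Holds R2, explained variance score (EVS), MSE, RMSE, MAE and MAPE (in
#' percent) for one observed/predicted pair. Metrics that are undefined for
#' the given data (zero observed values for MAPE; zero observed variance for
#' R2/EVS) are carried as \code{NA} with a flag, never silently dropped.
#'
#' @slot r2 numeric, coefficient of determination (<= 1, may be negative).
#' @slot evs numeric, explained variance score (population variance).
#' @slot mse numeric, mean squared error.
#' @slot rmse numeric, sqrt(mse).
#' @slot mae numeric, mean absolute error.
#' @slot mape numeric, mean absolute percentage error in percent.
#' @slot n integer, number of pairs.
#' @slot flags character vector naming undefined metrics.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(r2 = "numeric", evs = "numeric", mse = "numeric",
                        rmse = "numeric", mae = "numeric", mape = "numeric",
                        n = "integer", flags = "character"),
         validity = function(object) {
           if (!is.na(object@mse) && !is.na(object@rmse) &&
               abs(object@rmse - sqrt(object@mse)) > 1e-8 * (1 + object@mse))
             return("rmse must equal sqrt(mse)")
           if (!is.na(object@mape) && object@mape < 0)
             return("mape must be non-negative")
           if (!is.na(object@r2) && object@r2 > 1 + 1e-12)
             return("r2 cannot exceed 1")
           TRUE
         })

setMethod("show", "ReflectanceStack", function(object) {
  d <- dim(object@bands[[1L]])
  nNA <- sum(is.na(object@bands[[1L]]))
  cat(sprintf("ReflectanceStack: %d x %d pixels, month %d\n",
              d[1L], d[2L], object@month))
  cat("  bands:", paste(names(object@bands), collapse = " "), "\n")
  cat(sprintf("  masked pixels: %d (%.1f%%)\n", nNA, 100 * nNA / prod(d)))
})

setMethod("show", "IndexCube", function(object) {
  d <- dim(object@layers[[1L]])
  cat(sprintf("IndexCube: %d x %d pixels, month %d, 15 layers\n",
              d[1L], d[2L], object@month))
})

setMethod("show", "FparField", function(object) {
  v <- object@values
  cat(sprintf("FparField (%s), month %d: %d x %d pixels\n",
              object@source, object@month, nrow(v), ncol(v)))
  cat(sprintf("  range [%.3f, %.3f], %d masked\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "MeteoGrid", function(object) {
  cat(sprintf("MeteoGrid month %d: SOL mean %.1f MJ/m2, T mean %.1f degC, P mean %.1f mm\n",
              object@month, mean(object@sol, na.rm = TRUE),
              mean(object@temp, na.rm = TRUE),
              mean(object@precip, na.rm = TRUE)))
})

setMethod("show", "NppGrid", function(object) {
  cat(sprintf("NppGrid (%s): months %s\n", object@provenance,
              paste(names(object@monthly), collapse = " ")))
  cat(sprintf("  seasonal NPP mean %.1f gC/m2 over valid pixels\n",
              mean(object@annual, na.rm = TRUE)))
})

setMethod("show", "SceneTruth", function(object) {
  d <- dim(object@topt)
  cat(sprintf("SceneTruth: %d x %d pixels, season months %s, seed %s\n",
              d[1L], d[2L],
              paste(range(object@config$season), collapse = "-"),
              object@config$seed))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (n = %d)\n", object@n))
  cat(sprintf("  R2 %.4f | EVS %.4f | MSE %.6g | RMSE %.6g | MAE %.6g | MAPE %.2f%%\n",
              object@r2, object@evs, object@mse, object@rmse, object@mae,
              object@mape))
  if (length(object@flags))
    cat("  undefined:", paste(object@flags, collapse = ", "), "\n")
})
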