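#' @include scene.R
NULL

#' Read and write single-layer rasters as ESRI ASCII grids
#'
#' The interchange raster format is the plain-text ESRI ASCII grid
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value header, then rows
#' from the map top). Values, the nodata mask and the affine placement
#' round-trip exactly at the printed precision; the CRS travels in an
#' optional \code{.prj}-style sidecar line appended as a comment-free
#' companion file \code{<path>.crs}.
#'
#' @param path file path (conventionally \code{.asc}).
#' @param grid numeric matrix (NA = nodata).
#' @param georef georeference list from \code{\link{gridGeoref}}.
#' @param nodata nodata sentinel written to file (default -9999).
#' @param digits significant digits written (default 10).
#' @return \code{readAsciiGrid}: list(grid, georef);
#'   \code{writeAsciiGrid}: the path, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, georef = NULL, nodata = -9999,
                           digits = 10) {
  grid <- as.matrix(grid)
  if (is.null(georef)) georef <- gridGeoref(nrow(grid), ncol(grid))
  stopifnot(identical(dim(grid), c(georef$nrow, georef$ncol)))
  out <- grid
  out[is.na(out)] <- nodata
  hdr <- c(paste("ncols", georef$ncol), paste("nrows", georef$nrow),
           paste("xllcorner", format(georef$xll, digits = 15)),
           paste("yllcorner", format(georef$yll, digits = 15)),
           paste("cellsize", format(georef$cellsize, digits = 15)),
           paste("NODATA_value", nodata))
  body <- apply(out, 1L, function(r)
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, body), path)
  if (!is.null(georef$crs)) writeLines(georef$crs, paste0(path, ".crs"))
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) grid[grid == hdr$nodata_value] <- NA_real_
  crsFile <- paste0(path, ".crs")
  crs <- if (file.exists(crsFile)) readLines(crsFile)[1L] else NA_character_
  list(grid = grid,
       georef = gridGeoref(hdr$nrows, hdr$ncols, xll = hdr$xllcorner,
                           yll = hdr$yllcorner, cellsize = hdr$cellsize,
                           crs = crs))
}

#' Read and write multiband reflectance stacks
#'
#' A stack is a directory of per-band ASCII grids (\code{B2.asc}, ...)
#' plus a \code{stack.json} sidecar recording band order, acquisition
#' month and CRS. Round-trips values, mask and georeference.
#'
#' @param stack a \linkS4class{ReflectanceStack}.
#' @param dir directory path.
#' @return \code{readRasterStack}: a \linkS4class{ReflectanceStack}.
#' @export
writeRasterStack <- function(stack, dir) {
  stopifnot(is(stack, "ReflectanceStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(stack@bands))
    writeAsciiGrid(stack@bands[[b]], file.path(dir, paste0(b, ".asc")),
                   stack@georef)
  jsonlite::write_json(
    list(bands = names(stack@bands), month = stack@month,
         crs = stack@georef$crs),
    file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeRasterStack
#' @param expectedCrs optional CRS string; a mismatch with the stored CRS
#'   raises an error before any computation.
#' @export
readRasterStack <- function(dir, expectedCrs = NULL) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  grids <- lapply(meta$bands, function(b)
    readAsciiGrid(file.path(dir, paste0(b, ".asc"))))
  georef <- grids[[1L]]$georef
  georef$crs <- meta$crs
  if (!is.null(expectedCrs) && !identical(expectedCrs, meta$crs))
    stop("CRS mismatch: stack has '", meta$crs, "', expected '",
         expectedCrs, "'", call. = FALSE)
  bands <- lapply(grids, `[[`, "grid")
  names(bands) <- meta$bands
  reflectanceStack(bands, month = meta$month, georef = georef)
}

#' Write an IndexCube as per-layer ASCII grids
#' @param cube an \linkS4class{IndexCube}.
#' @param dir output directory.
#' @export
writeIndexCube <- function(cube, dir) {
  stopifnot(is(cube, "IndexCube"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cube@layers))
    writeAsciiGrid(cube@layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                   cube@georef)
  invisible(dir)
}

#' Export per-sample index values as CSV
#'
#' Columns: sample_id, lon, lat, month, then the 15 index columns (plus an
#' fpar column when labels are provided) -- the tabular training format.
#'
#' @param training a list from \code{\link{buildTrainingSet}}.
#' @param georef scene georeference for pixel-center coordinates.
#' @param path output CSV path.
#' @export
writeSampleCsv <- function(training, georef, path) {
  idx <- training$pixelIndex
  r <- ((idx - 1L) %% georef$nrow) + 1L
  cl <- ((idx - 1L) %/% georef$nrow) + 1L
  df <- data.frame(sample_id = seq_along(idx),
                   lon = georef$xll + (cl - 0.5) * georef$cellsize,
                   lat = georef$yll + (georef$nrow - r + 0.5) * georef$cellsize,
                   month = training$month)
  df <- cbind(df, as.data.frame(training$features$values))
  if (!is.null(training$y)) df$fpar <- training$y
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a trained FPAR model as a versioned text archive
#'
#' The archive is a single JSON file holding the model kind, the exact
#' feature order and scaling, the configuration, a config hash, and the
#' weights (CNN) or the xgboost dump (trees).
#'
#' @param model a \code{FparModel}.
#' @param path output path (.json).
#' @return \code{readFparModel}: the restored \code{FparModel}.
#' @export
writeFparModel <- function(model, path) {
  stopifnot(inherits(model, "FparModel"))
  payload <- list(format = "cropCASA-fpar-model", version = 1L,
                  kind = model$kind, featureNames = model$featureNames,
                  scaling = model$scaling[c("min", "max", "featureNames")],
                  report = reportAsList(model$report))
  if (model$kind == "cnn") {
    payload$config <- unclass(model$config)
    payload$net <- list(
      inputLen = model$net$inputLen, flat = model$net$flat,
      convs = lapply(model$net$convs, function(cv)
        list(W = as.vector(cv$W), dimW = dim(cv$W), b = cv$b)),
      dense = lapply(model$net$dense, function(dn)
        list(W = as.vector(dn$W), dimW = dim(dn$W), b = dn$b)))
  } else {
    payload$config <- model$config
    payload$nrounds <- model$nrounds
    payload$xgbRaw <- jsonlite::base64_enc(
      xgboost::xgb.save.raw(model$fit, raw_format = "ubj"))
  }
  payload$configHash <- .hashConfig(payload$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFparModel
#' @export
readFparModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$format, "cropCASA-fpar-model"))
    stop("not a cropCASA model archive: ", path, call. = FALSE)
  scaling <- list(min = setNames(as.numeric(p$scaling$min), p$featureNames),
                  max = setNames(as.numeric(p$scaling$max), p$featureNames),
                  featureNames = p$featureNames)
  num <- function(x) {      # undefined metrics arrive as null or "NA"
    if (is.null(x)) return(NA_real_)
    suppressWarnings(as.numeric(x))
  }
  report <- new("EvalReport", r2 = num(p$report$r2), evs = num(p$report$evs),
                mse = num(p$report$mse), rmse = num(p$report$rmse),
                mae = num(p$report$mae), mape = num(p$report$mape),
                n = as.integer(p$report$n),
                flags = as.character(p$report$flags %||% character(0)))
  if (p$kind == "cnn") {
    net <- list(
      inputLen = p$net$inputLen, flat = p$net$flat,
      convs = lapply(p$net$convs, function(cv)
        list(W = array(cv$W, dim = cv$dimW), b = as.numeric(cv$b))),
      dense = lapply(p$net$dense, function(dn)
        list(W = matrix(dn$W, dn$dimW[1L], dn$dimW[2L]),
             b = as.numeric(dn$b))))
    cfg <- p$config; class(cfg) <- "CnnConfig"
    model <- list(kind = "cnn", net = net, config = cfg,
                  featureNames = p$featureNames, scaling = scaling,
                  report = report)
  } else {
    fit <- xgboost::xgb.load.raw(jsonlite::base64_dec(p$xgbRaw))
    model <- list(kind = p$kind, fit = fit, config = p$config,
                  nrounds = p$nrounds, featureNames = p$featureNames,
                  scaling = scaling, report = report)
  }
  structure(model, class = "FparModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hashConfig <- function(cfg) {
  ## order-stable structural hash without external digest packages
  canon <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                            digits = 12)
  sum(utf8ToInt(as.character(canon)) * (seq_len(nchar(canon)) %% 251)) %%
    .Machine$integer.max
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Unknown top-level keys are rejected so typos fail before any stage runs.
#'
#' @param path config file path.
#' @return a validated named list of class \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  pipelineConfig(cfg)
}

.PIPELINE_KEYS <- c("scene", "indexParams", "model", "cnn", "tree",
                    "empirical", "season", "epsilonMax", "lat", "nSamples",
                    "rfeKeep", "seed", "outDir", "fparSource", "meteo")

#' @rdname readPipelineConfig
#' @param cfg named list of options; see Details.
#' @details Recognized keys: \code{scene} (sceneConfig overrides),
#'   \code{indexParams}, \code{model} ("cnn"/"gbdt"/"xgb"),
#'   \code{cnn} (cnnConfig overrides), \code{tree}, \code{empirical}
#'   (empiricalFparParams overrides), \code{season}, \code{epsilonMax},
#'   \code{lat}, \code{nSamples}, \code{rfeKeep}, \code{seed},
#'   \code{outDir}, \code{fparSource} ("cnn" or "empirical"), \code{meteo}.
#' @export
pipelineConfig <- function(cfg = list()) {
  unknown <- setdiff(names(cfg), .PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- list(model = "cnn", fparSource = "cnn", season = 4:10,
                   epsilonMax = 0.389, lat = 41, nSamples = 2756L,
                   rfeKeep = 15L, seed = 1L, outDir = NULL)
  out <- modifyList(defaults, cfg)
  stopifnot(out$fparSource %in% c("cnn", "empirical"),
            out$model %in% c("cnn", "gbdt", "xgb"))
  structure(out, class = "PipelineConfig")
}
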