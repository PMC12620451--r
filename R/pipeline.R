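#' @include io.R
NULL

#' Run the full NPP pipeline on a scene
#'
#' Executes the whole chain on a synthetic (or externally loaded) scene:
#' vegetation indices per month, training-set assembly against the scene's
#' FPAR labels, recursive feature elimination, CNN (or tree) training, FPAR
#' prediction per month, the empirical NDVI/RVI baseline, CASA NPP for both
#' FPAR sources, and evaluation against the scene truth. Returns all
#' in-memory artifacts plus a run manifest (config hash, seed, per-stage
#' metrics); when \code{cfg$outDir} is set, rasters, the sample CSV, the
#' model archive and the manifest JSON are also written there.
#'
#' NPP accuracy is scored on vegetated pixels (class map not "soil"):
#' bare-soil truth NPP is exactly zero, where a percentage error is
#' undefined.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param scene optional pre-built \linkS4class{SceneTruth}; by default a
#'   scene is generated from \code{cfg$scene} overrides with
#'   \code{cfg$seed}.
#' @return list with \code{scene}, \code{model}, \code{rfe}, \code{fpar}
#'   (per-month predicted fields), \code{fparEmpirical}, \code{npp},
#'   \code{nppEmpirical}, \code{evaluation}, \code{manifest}.
#' @export
runPipeline <- function(cfg = pipelineConfig(), scene = NULL) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (is.null(scene)) {
    scArgs <- modifyList(list(seed = cfg$seed, season = cfg$season,
                              epsilonMax = cfg$epsilonMax, lat = cfg$lat),
                         as.list(cfg$scene %||% list()))
    scene <- generateScene(do.call(sceneConfig, scArgs))
  }
  season <- scene@config$season
  keys <- as.character(season)
  ip <- do.call(indexParams, as.list(cfg$indexParams %||% list()))

  cubes <- lapply(scene@stacks, computeIndices, params = ip)

  training <- buildTrainingSet(scene, nSamples = cfg$nSamples, params = ip,
                               seed = cfg$seed)

  rfe <- rfeRank(training$features, training$y, nKeep = cfg$rfeKeep,
                 seed = cfg$seed)
  ## keep the canonical index order for the conv input layer
  selected <- indexNames()[indexNames() %in% rfe$selected]
  fmSel <- featureMatrix(training$features$values[, selected, drop = FALSE],
                         selected)

  model <- if (cfg$model == "cnn") {
    cnnArgs <- modifyList(list(seed = cfg$seed), as.list(cfg$cnn %||% list()))
    trainFparCnn(fmSel, training$y, do.call(cnnConfig, cnnArgs))
  } else {
    treeArgs <- modifyList(list(kind = cfg$model, seed = cfg$seed),
                           as.list(cfg$tree %||% list()))
    do.call(trainFparTree, c(list(fmSel, training$y), treeArgs))
  }

  fparPred <- lapply(cubes, function(cb) predictFpar(model, cb))
  empPar <- do.call(empiricalFparParams,
                    as.list(cfg$empirical %||% list()))
  fparEmp <- lapply(cubes, function(cb)
    empiricalFpar(indexLayer(cb, "NDVI"), indexLayer(cb, "RVI"),
                  params = empPar, month = cb@month, georef = cb@georef))

  npp <- runCasa(fparPred, scene@meteo, scene@topt,
                 epsilonMax = cfg$epsilonMax, season = season,
                 lat = cfg$lat, provenance = model$kind)
  nppEmp <- runCasa(fparEmp, scene@meteo, scene@topt,
                    epsilonMax = cfg$epsilonMax, season = season,
                    lat = cfg$lat, provenance = "empirical")

  veg <- scene@classMap != "soil"
  fparRmse <- function(fields) vapply(keys, function(k) {
    truthV <- scene@fpar[[k]]@values
    predV <- fields[[k]]@values
    ok <- !is.na(truthV) & !is.na(predV)
    sqrt(mean((truthV[ok] - predV[ok])^2))
  }, numeric(1))
  nppMape <- function(grid) {
    truthV <- nppAnnual(scene@npp)[veg]
    predV <- nppAnnual(grid)[veg]
    ok <- !is.na(truthV) & !is.na(predV) & truthV > 0
    100 * mean(abs((truthV[ok] - predV[ok]) / truthV[ok]))
  }
  evaluation <- list(
    fparRmse = fparRmse(fparPred),
    fparRmseEmpirical = fparRmse(fparEmp),
    heldOut = reportAsList(model$report),
    nppMape = nppMape(npp),
    nppMapeEmpirical = nppMape(nppEmp))

  manifest <- list(
    package = as.character(utils::packageVersion("cropCASA")),
    seed = cfg$seed, configHash = .hashConfig(unclass(cfg)[
      setdiff(names(unclass(cfg)), "outDir")]),
    model = cfg$model, fparSource = cfg$fparSource,
    selectedFeatures = rfe$selected,
    metrics = list(
      fparRmseMean = mean(evaluation$fparRmse),
      fparRmseEmpiricalMean = mean(evaluation$fparRmseEmpirical),
      heldOutR2 = evaluation$heldOut$r2,
      heldOutMae = evaluation$heldOut$mae,
      nppMape = evaluation$nppMape,
      nppMapeEmpirical = evaluation$nppMapeEmpirical))

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    chosenNpp <- if (cfg$fparSource == "empirical") nppEmp else npp
    for (k in keys) {
      writeAsciiGrid(fparValues(fparPred[[k]]),
                     file.path(cfg$outDir, sprintf("fpar_%s.asc", k)),
                     scene@georef)
      writeAsciiGrid(nppMonthly(chosenNpp, k),
                     file.path(cfg$outDir, sprintf("npp_%s.asc", k)),
                     scene@georef)
    }
    writeAsciiGrid(nppAnnual(chosenNpp),
                   file.path(cfg$outDir, "npp_season.asc"), scene@georef)
    writeSampleCsv(training, scene@georef,
                   file.path(cfg$outDir, "samples.csv"))
    writeFparModel(model, file.path(cfg$outDir, "fpar_model.json"))
    zonal <- data.frame(class = c("rice", "corn", "forest"),
                        meanNpp = vapply(c("rice", "corn", "forest"),
                          function(cl) mean(nppAnnual(chosenNpp)[
                            scene@classMap == cl], na.rm = TRUE),
                          numeric(1)))
    write.csv(zonal, file.path(cfg$outDir, "npp_zonal.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(scene = scene, model = model, rfe = rfe, fpar = fparPred,
       fparEmpirical = fparEmp, npp = npp, nppEmpirical = nppEmp,
       evaluation = evaluation, manifest = manifest)
}
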