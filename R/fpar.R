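#' @include cnn.R indices.R metrics.R
NULL

#' Feature matrix of vegetation-index samples
#'
#' @param values numeric matrix, samples x features, no missing values.
#' @param featureNames unique column names (defaults to colnames).
#' @return list of class \code{FeatureMatrix} with \code{values},
#'   \code{featureNames} and an empty \code{scaling} slot.
#' @export
featureMatrix <- function(values, featureNames = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(featureNames))
    stop("feature names are required", call. = FALSE)
  if (anyDuplicated(featureNames))
    stop("feature names must be unique", call. = FALSE)
  if (length(featureNames) != ncol(values))
    stop("featureNames length must match the number of columns",
         call. = FALSE)
  if (anyNA(values))
    stop("feature matrix must be free of missing values (mask-filter first)",
         call. = FALSE)
  colnames(values) <- featureNames
  structure(list(values = values, featureNames = featureNames,
                 scaling = NULL),
            class = "FeatureMatrix")
}

#' Min-max normalize features to [0, 1]
#'
#' Records the per-feature (min, max) so the same affine map can be applied
#' to new data at prediction time; \code{\link{applyScaling}} and
#' \code{\link{invertScaling}} round-trip exactly. Constant features carry
#' no information and are dropped with a warning.
#'
#' @param m a \code{\link{featureMatrix}}.
#' @return a FeatureMatrix scaled to [0,1] with \code{scaling} recorded.
#' @export
normalizeFeatures <- function(m) {
  stopifnot(inherits(m, "FeatureMatrix"))
  mins <- apply(m$values, 2L, min)
  maxs <- apply(m$values, 2L, max)
  const <- maxs - mins <= 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(m$featureNames[const], collapse = ", "), call. = FALSE)
    m$values <- m$values[, !const, drop = FALSE]
    m$featureNames <- m$featureNames[!const]
    mins <- mins[!const]; maxs <- maxs[!const]
  }
  if (!length(m$featureNames))
    stop("all features are constant", call. = FALSE)
  scl <- list(min = mins, max = maxs, featureNames = m$featureNames)
  m$values <- applyScaling(m$values, scl)
  m$scaling <- scl
  m
}

#' @rdname normalizeFeatures
#' @param values raw feature matrix whose columns cover
#'   \code{scaling$featureNames}.
#' @param scaling the scaling record from \code{normalizeFeatures}.
#' @export
applyScaling <- function(values, scaling) {
  values <- as.matrix(values)[, scaling$featureNames, drop = FALSE]
  sweep(sweep(values, 2L, scaling$min), 2L, scaling$max - scaling$min, `/`)
}

#' @rdname normalizeFeatures
#' @export
invertScaling <- function(values, scaling) {
  values <- as.matrix(values)
  sweep(sweep(values, 2L, scaling$max - scaling$min, `*`), 2L,
        scaling$min, `+`)
}

.xgbFit <- function(X, y, nrounds, params, seed) {
  set.seed(seed)
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
                     nrounds = nrounds)
}

.xgbImportance <- function(fit, featureNames) {
  imp <- xgboost::xgb.importance(model = fit)
  out <- setNames(numeric(length(featureNames)), featureNames)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  out
}

.xgbCvRmse <- function(X, y, nrounds, params, seed, nfold = 5L) {
  set.seed(seed)
  fold <- sample(rep_len(seq_len(nfold), nrow(X)))
  errs <- vapply(seq_len(nfold), function(f) {
    tr <- fold != f
    fit <- .xgbFit(X[tr, , drop = FALSE], y[tr], nrounds, params, seed + f)
    p <- predict(fit, X[!tr, , drop = FALSE])
    sqrt(mean((p - y[!tr])^2))
  }, numeric(1))
  mean(errs)
}

#' Recursive feature elimination with a gradient-boosted base estimator
#'
#' Fits gradient-boosted trees on the current feature set, scores it by
#' 5-fold cross-validated RMSE, removes the feature with the smallest gain
#' importance, and repeats until \code{nKeep} features remain. Deterministic
#' given the seed.
#'
#' @param m a \code{\link{featureMatrix}}.
#' @param y numeric response vector (e.g. FPAR in [0, 1]).
#' @param nKeep number of features to retain, in [1, n_features].
#' @param seed RNG seed.
#' @param nrounds boosting rounds of the base estimator.
#' @param maxDepth tree depth of the base estimator.
#' @param eta learning rate of the base estimator.
#' @return list of class \code{RfeResult}: \code{ranking} (named integer,
#'   1 = most important), \code{selected} (feature names ordered by rank),
#'   \code{scores} (CV RMSE per elimination step, named by the set size
#'   scored), \code{eliminated} (names in elimination order).
#' @export
rfeRank <- function(m, y, nKeep, seed = 42L, nrounds = 60L, maxDepth = 3L,
                    eta = 0.3) {
  stopifnot(inherits(m, "FeatureMatrix"))
  y <- as.numeric(y)
  nf <- length(m$featureNames)
  if (nKeep < 1L || nKeep > nf)
    stop("nKeep must lie in [1, ", nf, "]", call. = FALSE)
  if (nrow(m$values) != length(y))
    stop("response length must match the number of samples", call. = FALSE)
  params <- list(max_depth = maxDepth, eta = eta, nthread = 1L,
                 objective = "reg:squarederror")
  current <- m$featureNames
  eliminated <- character(0)
  scores <- numeric(0)
  step <- 0L
  while (length(current) > nKeep) {
    X <- m$values[, current, drop = FALSE]
    scores[as.character(length(current))] <-
      .xgbCvRmse(X, y, nrounds, params, seed + step)
    fit <- .xgbFit(X, y, nrounds, params, seed + step)
    imp <- .xgbImportance(fit, current)
    drop <- names(which.min(imp))           # stable: first minimum
    eliminated <- c(eliminated, drop)
    current <- setdiff(current, drop)
    step <- step + 1L
  }
  X <- m$values[, current, drop = FALSE]
  scores[as.character(length(current))] <-
    .xgbCvRmse(X, y, nrounds, params, seed + step)
  finalImp <- .xgbImportance(.xgbFit(X, y, nrounds, params, seed + step),
                             current)
  selected <- names(sort(finalImp, decreasing = TRUE))
  ranking <- setNames(seq_len(nf),
                      c(selected, rev(eliminated)))[m$featureNames]
  structure(list(ranking = ranking, selected = selected, scores = scores,
                 eliminated = eliminated),
            class = "RfeResult")
}

.splitIndices <- function(n, splitRatio, seed) {
  set.seed(seed)
  ord <- sample.int(n)
  nTrain <- floor(n * splitRatio)
  list(train = ord[seq_len(nTrain)], test = ord[-seq_len(nTrain)])
}

.heldOutReport <- function(yTest, pred) {
  evaluatePredictions(yTest, pred)
}

#' Train the 1-D CNN FPAR regressor
#'
#' Normalizes features (unless the matrix already carries a scaling),
#' splits samples 7:3 by a seeded shuffle, trains the convolutional network
#' described in \code{\link{cnnConfig}} and reports held-out R2, EVS, MSE,
#' RMSE, MAE (and MAPE when defined). FPAR targets stay in their native
#' [0, 1] scale.
#'
#' @param m a \code{\link{featureMatrix}} (raw or already normalized).
#' @param y FPAR response vector in [0, 1].
#' @param config a \code{\link{cnnConfig}}.
#' @param verbose print per-epoch training loss.
#' @return a \code{FparModel} (kind "cnn") with the network weights, the
#'   expected feature order and scaling, and the held-out
#'   \linkS4class{EvalReport} in \code{$report}.
#' @export
trainFparCnn <- function(m, y, config = cnnConfig(), verbose = FALSE) {
  stopifnot(inherits(m, "FeatureMatrix"), inherits(config, "CnnConfig"))
  y <- as.numeric(y)
  n <- nrow(m$values)
  if (n != length(y))
    stop("response length must match the number of samples", call. = FALSE)
  if (n < 2L * config$batchSize)
    stop("need at least two batches of samples (", 2L * config$batchSize,
         "); got ", n, call. = FALSE)
  if (any(y < -1e-9 | y > 1 + 1e-9, na.rm = TRUE))
    stop("FPAR targets must lie in [0, 1]", call. = FALSE)
  if (is.null(m$scaling)) m <- normalizeFeatures(m)

  sp <- .splitIndices(n, config$splitRatio, config$seed)
  set.seed(config$seed)
  net <- .cnnFit(m$values[sp$train, , drop = FALSE], y[sp$train], config,
                 verbose = verbose)
  pred <- pmin(pmax(.cnnPredict(net, m$values[sp$test, , drop = FALSE],
                                config), 0), 1)
  report <- .heldOutReport(y[sp$test], pred)
  structure(list(kind = "cnn", net = net, config = config,
                 featureNames = m$featureNames, scaling = m$scaling,
                 report = report, split = sp),
            class = "FparModel")
}

#' Train a gradient-boosted tree FPAR baseline
#'
#' Same split protocol and report as \code{\link{trainFparCnn}}; the two
#' kinds are hyperparameter presets of gradient-boosted regression trees
#' ("gbdt": full-sample deterministic boosting; "xgb": row/column
#' subsampling with L2 regularization).
#'
#' @inheritParams trainFparCnn
#' @param kind "gbdt" or "xgb".
#' @param nrounds,maxDepth,eta boosting hyperparameters (defaults: 500
#'   trees, depth 6, learning rate 0.05).
#' @param splitRatio,seed split protocol.
#' @return a \code{FparModel} of the requested kind.
#' @export
trainFparTree <- function(m, y, kind = c("gbdt", "xgb"), nrounds = 500L,
                          maxDepth = 6L, eta = 0.05, splitRatio = 0.7,
                          seed = 42L) {
  kind <- match.arg(kind)
  stopifnot(inherits(m, "FeatureMatrix"))
  y <- as.numeric(y)
  n <- nrow(m$values)
  if (n != length(y))
    stop("response length must match the number of samples", call. = FALSE)
  if (is.null(m$scaling)) m <- normalizeFeatures(m)
  params <- list(max_depth = maxDepth, eta = eta, nthread = 1L,
                 objective = "reg:squarederror")
  if (kind == "xgb")
    params <- c(params, list(subsample = 0.8, colsample_bytree = 0.8,
                             lambda = 1))
  sp <- .splitIndices(n, splitRatio, seed)
  fit <- .xgbFit(m$values[sp$train, , drop = FALSE], y[sp$train], nrounds,
                 params, seed)
  pred <- pmin(pmax(predict(fit, m$values[sp$test, , drop = FALSE]), 0), 1)
  report <- .heldOutReport(y[sp$test], pred)
  structure(list(kind = kind, fit = fit, config = params, nrounds = nrounds,
                 featureNames = m$featureNames, scaling = m$scaling,
                 report = report, split = sp),
            class = "FparModel")
}

#' @export
print.FparModel <- function(x, ...) {
  cat(sprintf("FparModel <%s>: %d features (%s)\n", x$kind,
              length(x$featureNames),
              paste(x$featureNames, collapse = " ")))
  cat("held-out report:\n")
  show(x$report)
  invisible(x)
}

#' Predict FPAR from a trained model
#'
#' Applies the model's recorded feature scaling, evaluates the network or
#' tree ensemble, and clips the raw output to [0, 1]. A matrix (or
#' FeatureMatrix) yields an FPAR vector; an \linkS4class{IndexCube} yields
#' an \linkS4class{FparField} grid in which masked pixels stay masked.
#'
#' @param model a \code{FparModel}.
#' @param newdata raw feature matrix, \code{\link{featureMatrix}}, or
#'   \linkS4class{IndexCube}.
#' @return numeric vector in [0, 1], or an \linkS4class{FparField}.
#' @export
predictFpar <- function(model, newdata) {
  stopifnot(inherits(model, "FparModel"))
  if (is(newdata, "IndexCube")) {
    ft <- cubeToFeatures(newdata)
    vals <- .predictFparMatrix(model, ft$values, ft$featureNames)
    grid <- matrix(NA_real_, ft$dim[1L], ft$dim[2L])
    grid[ft$pixelIndex] <- vals
    return(fparField(grid, month = newdata@month, source = model$kind,
                     georef = newdata@georef))
  }
  if (inherits(newdata, "FeatureMatrix")) {
    return(.predictFparMatrix(model, newdata$values, newdata$featureNames))
  }
  newdata <- as.matrix(newdata)
  .predictFparMatrix(model, newdata, colnames(newdata))
}

.predictFparMatrix <- function(model, values, featureNames) {
  missing <- setdiff(model$featureNames, featureNames)
  if (length(missing))
    stop("newdata lacks feature(s) the model expects: ",
         paste(missing, collapse = ", "), call. = FALSE)
  colnames(values) <- featureNames
  X <- applyScaling(values, model$scaling)
  raw <- if (model$kind == "cnn") .cnnPredict(model$net, X, model$config)
         else predict(model$fit, X)
  pmin(pmax(raw, 0), 1)
}

#' Parameters of the empirical NDVI/RVI FPAR stretch
#'
#' The classical CASA FPAR: NDVI (and the simple ratio RVI) are linearly
#' stretched between scene bounds onto [fpar_min, fpar_max] and the two
#' estimates are blended with weight alpha. Stretch bounds left NA are
#' filled per scene from the 5th/95th percentiles of vegetated pixels
#' (NDVI above \code{vegNdvi}).
#'
#' @param ndvi_min,ndvi_max,sr_min,sr_max stretch bounds (NA = per-scene
#'   percentiles).
#' @param fpar_min,fpar_max output bounds (defaults 0.001 and 0.95).
#' @param alpha NDVI-vs-SR blending weight in [0, 1] (default 0.5).
#' @param vegNdvi NDVI threshold defining vegetated pixels for the
#'   percentile bounds (default 0.2).
#' @return a validated list of class \code{EmpiricalFparParams}.
#' @export
empiricalFparParams <- function(ndvi_min = NA, ndvi_max = NA, sr_min = NA,
                                sr_max = NA, fpar_min = 0.001,
                                fpar_max = 0.95, alpha = 0.5,
                                vegNdvi = 0.2) {
  stopifnot(fpar_min >= 0, fpar_max <= 1, fpar_min < fpar_max,
            alpha >= 0, alpha <= 1)
  if (!is.na(ndvi_min) && !is.na(ndvi_max) && ndvi_max <= ndvi_min)
    stop("ndvi_max must exceed ndvi_min", call. = FALSE)
  if (!is.na(sr_min) && !is.na(sr_max) && sr_max <= sr_min)
    stop("sr_max must exceed sr_min", call. = FALSE)
  structure(list(ndvi_min = ndvi_min, ndvi_max = ndvi_max, sr_min = sr_min,
                 sr_max = sr_max, fpar_min = fpar_min, fpar_max = fpar_max,
                 alpha = alpha, vegNdvi = vegNdvi),
            class = "EmpiricalFparParams")
}

.stretch <- function(x, lo, hi, fmin, fmax) {
  out <- (x - lo) * (fmax - fmin) / (hi - lo) + fmin
  pmin(pmax(out, fmin), fmax)
}

#' Empirical NDVI/RVI FPAR (original-CASA baseline)
#'
#' FPAR_NDVI and FPAR_SR are linear stretches of NDVI and RVI between the
#' scene bounds, clamped to [fpar_min, fpar_max], and blended as
#' alpha x FPAR_NDVI + (1 - alpha) x FPAR_SR.
#'
#' @param ndvi NDVI grid.
#' @param rvi RVI (simple ratio) grid.
#' @param params an \code{\link{empiricalFparParams}}.
#' @param month month recorded on the output field.
#' @param georef georeference for the output field.
#' @return an \linkS4class{FparField} (source "empirical").
#' @export
empiricalFpar <- function(ndvi, rvi, params = empiricalFparParams(),
                          month = 1L, georef = NULL) {
  ndvi <- as.matrix(ndvi); rvi <- as.matrix(rvi)
  p <- params
  veg <- !is.na(ndvi) & ndvi > p$vegNdvi
  fillBounds <- function(lo, hi, x) {
    if (is.na(lo) || is.na(hi)) {
      if (!any(veg))
        stop("no vegetated pixels to derive stretch bounds from; ",
             "set bounds explicitly", call. = FALSE)
      q <- quantile(x[veg], c(0.05, 0.95), na.rm = TRUE, names = FALSE)
      lo <- if (is.na(lo)) q[1L] else lo
      hi <- if (is.na(hi)) q[2L] else hi
    }
    if (hi - lo <= 1e-12)
      stop("degenerate stretch bounds (max <= min)", call. = FALSE)
    c(lo, hi)
  }
  nb <- fillBounds(p$ndvi_min, p$ndvi_max, ndvi)
  sb <- fillBounds(p$sr_min, p$sr_max, rvi)
  fN <- .stretch(ndvi, nb[1L], nb[2L], p$fpar_min, p$fpar_max)
  fS <- .stretch(rvi, sb[1L], sb[2L], p$fpar_min, p$fpar_max)
  out <- p$alpha * fN + (1 - p$alpha) * fS
  out[is.na(ndvi) | is.na(rvi)] <- NA_real_
  fparField(out, month = month, source = "empirical", georef = georef)
}
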