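#' @include AllClasses.R
NULL

#' Evaluate predictions: R2, EVS, MSE, RMSE, MAE, MAPE
#'
#' The suite used for both FPAR and NPP validation.
#' \deqn{R^2 = 1 - \sum_i(\hat y_i - y_i)^2 / \sum_i(y_i - \bar y)^2}
#' \deqn{EVS = 1 - Var(y - \hat y) / Var(y)}
#' with population (1/n) variances, \eqn{MSE = (1/n)\sum (y-\hat y)^2},
#' \eqn{MAE = (1/n)\sum |y-\hat y|}, and
#' \eqn{MAPE = (100/n)\sum |(y-\hat y)/y|} in percent. EVS equals R2
#' whenever the mean residual is zero. Undefined metrics (MAPE with a zero
#' observation, R2/EVS with zero observed variance) are reported as NA and
#' named in the report's \code{flags}; the remaining metrics are still
#' computed.
#'
#' @param observed numeric vector of reference values.
#' @param predicted numeric vector of model values, same length.
#' @param na.rm drop pairs where either value is NA (default TRUE).
#' @return an \linkS4class{EvalReport}.
#' @examples
#' evaluatePredictions(c(1, 2, 3), c(1, 2, 4))
#' @export
evaluatePredictions <- function(observed, predicted, na.rm = TRUE) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (na.rm) {
    keep <- !(is.na(observed) | is.na(predicted))
    observed <- observed[keep]; predicted <- predicted[keep]
  }
  n <- length(observed)
  if (n < 2L)
    stop("need at least 2 observation pairs", call. = FALSE)

  res <- observed - predicted
  mse <- mean(res^2)
  mae <- mean(abs(res))
  flags <- character(0)

  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot <= 0) {
    r2 <- NA_real_; evs <- NA_real_
    flags <- c(flags, "r2", "evs")
  } else {
    r2 <- 1 - sum(res^2) / ssTot
    ## population variances: Var(y - yhat) / Var(y)
    evs <- 1 - mean((res - mean(res))^2) / mean((observed - mean(observed))^2)
  }

  if (any(observed == 0)) {
    mape <- NA_real_
    flags <- c(flags, "mape")
  } else {
    mape <- 100 * mean(abs(res / observed))
  }

  new("EvalReport", r2 = r2, evs = evs, mse = mse, rmse = sqrt(mse),
      mae = mae, mape = mape, n = n, flags = flags)
}
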