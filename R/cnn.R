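#' @include constructors.R
NULL

## ---------------------------------------------------------------------------
## A small 1-D convolutional network for tabular spectral-index regression,
## implemented natively with vectorized array algebra: conv (kernel 2, 'same'
## zero padding) -> ReLU -> max-pool (size 2, stride 2, ceil) three times,
## flatten, inverted dropout, then a dense stack with a linear scalar output.
## Trained with Adam on MSE. Activations are (batch, length, channels) arrays;
## each conv tap is one matrix multiplication, so batches are fast in pure R.
## ---------------------------------------------------------------------------

#' CNN configuration
#'
#' Defaults follow the optimized architecture used for FPAR regression:
#' three conv layers with 16/32/64 filters of kernel size 2, max-pooling
#' after each, dropout 0.3 before the dense stack, three dense layers
#' (64, 32, then the scalar linear output), Adam at learning rate 0.001,
#' MSE loss, 10 epochs, 7:3 train/test split. The batch size (32) and
#' Glorot-uniform initialization are implementation choices made for stable
#' convergence at a few thousand samples.
#'
#' @param convFilters integer vector of conv filter counts.
#' @param kernelSize conv kernel width.
#' @param denseUnits hidden dense layer sizes (the scalar output is added).
#' @param dropout dropout rate in [0, 1) applied before the dense stack.
#' @param learningRate Adam step size.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param splitRatio train fraction of the seeded 7:3 shuffle split.
#' @param seed RNG seed for the split, initialization and dropout.
#' @return a validated list of class \code{CnnConfig}.
#' @export
cnnConfig <- function(convFilters = c(16L, 32L, 64L), kernelSize = 2L,
                      denseUnits = c(64L, 32L), dropout = 0.3,
                      learningRate = 0.001, epochs = 10L, batchSize = 32L,
                      splitRatio = 0.7, seed = 42L) {
  stopifnot(splitRatio > 0, splitRatio < 1, epochs >= 1,
            dropout >= 0, dropout < 1, kernelSize >= 1,
            all(convFilters >= 1), batchSize >= 1)
  structure(list(convFilters = as.integer(convFilters),
                 kernelSize = as.integer(kernelSize),
                 denseUnits = as.integer(denseUnits), dropout = dropout,
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), splitRatio = splitRatio,
                 seed = as.integer(seed)),
            class = "CnnConfig")
}

## Glorot-uniform initialization (the usual deep-learning-framework
## default); converges faster here than He-normal within the 10-epoch budget.
.cnnInit <- function(inputLen, cfg) {
  k <- cfg$kernelSize
  gu <- function(fanIn, fanOut, n) runif(n, -1, 1) * sqrt(6 / (fanIn + fanOut))
  convs <- list()
  inCh <- 1L
  len <- inputLen
  for (f in cfg$convFilters) {
    convs[[length(convs) + 1L]] <- list(
      W = array(gu(k * inCh, k * f, k * inCh * f), dim = c(k, inCh, f)),
      b = numeric(f))
    inCh <- f
    len <- ceiling(len / 2)        # pool
  }
  flat <- len * inCh
  dims <- c(flat, cfg$denseUnits, 1L)
  dense <- lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = matrix(gu(dims[i], dims[i + 1L], dims[i] * dims[i + 1L]),
                    dims[i], dims[i + 1L]),
         b = numeric(dims[i + 1L]))
  })
  list(convs = convs, dense = dense, inputLen = inputLen, flat = flat)
}

## conv with 'same' zero padding at the end (kernel 2 needs one pad column)
.convForward <- function(X, W, b) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; inCh <- d[3L]
  k <- dim(W)[1L]; outCh <- dim(W)[3L]
  Xpad <- array(0, dim = c(B, L + k - 1L, inCh))
  Xpad[, seq_len(L), ] <- X
  Ymat <- matrix(rep(b, each = B * L), B * L, outCh)
  for (t in seq_len(k)) {
    Xt <- Xpad[, t:(t + L - 1L), , drop = FALSE]
    dim(Xt) <- c(B * L, inCh)
    Ymat <- Ymat + Xt %*% matrix(W[t, , ], inCh, outCh)
  }
  array(Ymat, dim = c(B, L, outCh))
}

.convBackward <- function(X, W, dY) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; inCh <- d[3L]
  k <- dim(W)[1L]; outCh <- dim(W)[3L]
  Xpad <- array(0, dim = c(B, L + k - 1L, inCh))
  Xpad[, seq_len(L), ] <- X
  dYmat <- dY; dim(dYmat) <- c(B * L, outCh)
  dW <- array(0, dim = dim(W))
  dXpad <- array(0, dim = dim(Xpad))
  for (t in seq_len(k)) {
    Xt <- Xpad[, t:(t + L - 1L), , drop = FALSE]
    dim(Xt) <- c(B * L, inCh)
    dW[t, , ] <- crossprod(Xt, dYmat)
    dXt <- dYmat %*% t(matrix(W[t, , ], inCh, outCh))
    dim(dXt) <- c(B, L, inCh)
    dXpad[, t:(t + L - 1L), ] <-
      dXpad[, t:(t + L - 1L), , drop = FALSE] + dXt
  }
  list(dX = dXpad[, seq_len(L), , drop = FALSE],
       dW = dW, db = colSums(dYmat))
}

## max-pool size 2 stride 2, ceil (odd tail passes through)
.poolForward <- function(X) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]
  i1 <- seq(1L, L, by = 2L)
  i2 <- pmin(i1 + 1L, L)                 # odd tail: compare with itself
  X1 <- X[, i1, , drop = FALSE]
  X2 <- X[, i2, , drop = FALSE]
  tail1 <- i1 + 1L > L                   # positions with no real partner
  takeFirst <- (X1 >= X2)
  if (any(tail1)) takeFirst[, tail1, ] <- TRUE
  list(Y = pmax(X1, X2), takeFirst = takeFirst, i1 = i1, i2 = i2, L = L)
}

.poolBackward <- function(cache, dY) {
  d <- dim(dY); B <- d[1L]; C <- d[3L]
  dX <- array(0, dim = c(B, cache$L, C))
  dX[, cache$i1, ] <- dY * cache$takeFirst
  sel2 <- dY * !cache$takeFirst
  dX[, cache$i2, ] <- dX[, cache$i2, , drop = FALSE] + sel2
  dX
}

.cnnForward <- function(net, X, cfg, training = FALSE) {
  B <- nrow(X)
  A <- array(X, dim = c(B, ncol(X), 1L))
  caches <- list()
  for (i in seq_along(net$convs)) {
    Z <- .convForward(A, net$convs[[i]]$W, net$convs[[i]]$b)
    R <- pmax(Z, 0)
    pc <- .poolForward(R)
    caches[[i]] <- list(Ain = A, Z = Z, pool = pc)
    A <- pc$Y
  }
  flat <- A; dim(flat) <- c(B, net$flat)
  dropMask <- NULL
  if (training && cfg$dropout > 0) {
    dropMask <- matrix(runif(length(flat)) >= cfg$dropout,
                       nrow(flat), ncol(flat)) / (1 - cfg$dropout)
    flat <- flat * dropMask
  }
  H <- flat
  denseCaches <- list()
  nd <- length(net$dense)
  for (j in seq_len(nd)) {
    Zd <- sweep(H %*% net$dense[[j]]$W, 2L, net$dense[[j]]$b, `+`)
    denseCaches[[j]] <- list(Hin = H, Zd = Zd)
    H <- if (j < nd) pmax(Zd, 0) else Zd       # linear scalar output
  }
  list(pred = drop(H), convCaches = caches, flat = flat,
       dropMask = dropMask, denseCaches = denseCaches)
}

.cnnBackward <- function(net, fw, dPred, cfg) {
  B <- length(dPred)
  nd <- length(net$dense)
  grads <- list(convs = vector("list", length(net$convs)),
                dense = vector("list", nd))
  dH <- matrix(dPred, B, 1L)
  for (j in rev(seq_len(nd))) {
    cc <- fw$denseCaches[[j]]
    dZ <- if (j < nd) dH * (cc$Zd > 0) else dH
    grads$dense[[j]] <- list(dW = crossprod(cc$Hin, dZ), db = colSums(dZ))
    dH <- dZ %*% t(net$dense[[j]]$W)
  }
  if (!is.null(fw$dropMask)) dH <- dH * fw$dropMask
  nc <- length(net$convs)
  lastPool <- fw$convCaches[[nc]]$pool
  dA <- array(dH, dim = dim(lastPool$Y))
  for (i in rev(seq_len(nc))) {
    cc <- fw$convCaches[[i]]
    dR <- .poolBackward(cc$pool, dA)
    dZ <- dR * (cc$Z > 0)
    cb <- .convBackward(cc$Ain, net$convs[[i]]$W, dZ)
    grads$convs[[i]] <- list(dW = cb$dW, db = cb$db)
    if (i > 1L) dA <- cb$dX
  }
  grads
}

.adamInit <- function(net) {
  zero <- function(p) list(W = array(0, dim = dim(p$W)) ,
                           b = numeric(length(p$b)))
  list(m = list(convs = lapply(net$convs, zero),
                dense = lapply(net$dense, zero)),
       v = list(convs = lapply(net$convs, zero),
                dense = lapply(net$dense, zero)),
       t = 0L)
}

.adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m$W <- beta1 * m$W + (1 - beta1) * g$dW
    m$b <- beta1 * m$b + (1 - beta1) * g$db
    v$W <- beta2 * v$W + (1 - beta2) * g$dW^2
    v$b <- beta2 * v$b + (1 - beta2) * g$db^2
    p$W <- p$W - lr * (m$W / bc1) / (sqrt(v$W / bc2) + eps)
    p$b <- p$b - lr * (m$b / bc1) / (sqrt(v$b / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(net$convs)) {
    r <- upd(net$convs[[i]], grads$convs[[i]],
             state$m$convs[[i]], state$v$convs[[i]])
    net$convs[[i]] <- r$p; state$m$convs[[i]] <- r$m
    state$v$convs[[i]] <- r$v
  }
  for (j in seq_along(net$dense)) {
    r <- upd(net$dense[[j]], grads$dense[[j]],
             state$m$dense[[j]], state$v$dense[[j]])
    net$dense[[j]] <- r$p; state$m$dense[[j]] <- r$m
    state$v$dense[[j]] <- r$v
  }
  list(net = net, state = state)
}

## One full training run; X already normalized, y in [0,1].
.cnnFit <- function(X, y, cfg, verbose = FALSE) {
  net <- .cnnInit(ncol(X), cfg)
  ## start the output bias at the target mean: centred residual learning
  net$dense[[length(net$dense)]]$b <- mean(y)
  state <- .adamInit(net)
  n <- nrow(X)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batchSize)
    epLoss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- .cnnForward(net, Xb, cfg, training = TRUE)
      res <- fw$pred - yb
      if (!all(is.finite(res)))
        stop("non-finite training loss at epoch ", ep,
             "; check feature scaling", call. = FALSE)
      epLoss <- epLoss + sum(res^2)
      grads <- .cnnBackward(net, fw, 2 * res / length(res), cfg)
      r <- .adamStep(net, grads, state, cfg$learningRate)
      net <- r$net; state <- r$state
    }
    if (verbose)
      message(sprintf("epoch %d/%d  train MSE %.6f", ep, cfg$epochs,
                      epLoss / n))
  }
  net
}

.cnnPredict <- function(net, X, cfg) {
  ## predict in chunks to bound memory on large grids
  n <- nrow(X)
  out <- numeric(n)
  for (s in seq(1L, n, by = 4096L)) {
    idx <- s:min(s + 4095L, n)
    out[idx] <- .cnnForward(net, X[idx, , drop = FALSE], cfg,
                            training = FALSE)$pred
  }
  out
}
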