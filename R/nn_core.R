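# Minimal CNN-LSTM engine: forward passes, analytic backpropagation and Adam
# updates for the layer types used by the two sub-networks (1-D convolution,
# non-overlapping max-pooling, a unidirectional LSTM, dense layers with
# ReLU/tanh/linear activations and inverted dropout). Batches are dense
# arrays: (batch, length, channels) for convolutional input, (batch, units)
# after the LSTM. Everything is plain vectorized R on BLAS-backed matrix
# products; analytic gradients are validated against central differences in
# the test suite.

stableSigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  dim(out) <- dim(x)
  out
}

glorotMatrix <- function(nr, nc, fanIn = nr, fanOut = nc) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

## ---- layer constructors -------------------------------------------------

nnConv1d <- function(inChannels, nFilters, filterWidth, activation = "relu") {
  stopifnot(inChannels >= 1, nFilters >= 1, filterWidth >= 1)
  list(type = "conv1d",
       W = glorotMatrix(filterWidth * inChannels, nFilters,
                        fanIn = filterWidth * inChannels, fanOut = nFilters),
       b = numeric(nFilters),
       filterWidth = filterWidth, inChannels = inChannels,
       nFilters = nFilters, activation = activation, frozen = FALSE)
}

nnMaxPool <- function(poolWidth) {
  stopifnot(poolWidth >= 1)
  list(type = "maxpool", poolWidth = poolWidth, frozen = FALSE)
}

nnLSTM <- function(inSize, units) {
  stopifnot(inSize >= 1, units >= 1)
  b <- numeric(4 * units)
  b[units + seq_len(units)] <- 1  # forget-gate bias init
  list(type = "lstm",
       Wx = glorotMatrix(inSize, 4 * units, fanIn = inSize, fanOut = units),
       Wh = glorotMatrix(units, 4 * units, fanIn = units, fanOut = units),
       b = b, inSize = inSize, units = units, frozen = FALSE)
}

nnDense <- function(inSize, units, activation = "linear", dropout = 0) {
  stopifnot(inSize >= 1, units >= 1, dropout >= 0, dropout < 1)
  list(type = "dense",
       W = glorotMatrix(inSize, units),
       b = numeric(units),
       inSize = inSize, units = units,
       activation = activation, dropout = dropout, frozen = FALSE)
}

# a "stack" is a plain list: $layers plus optional metadata ($config, ...)
nnStack <- function(...) {
  list(layers = list(...))
}

## ---- conv ---------------------------------------------------------------

# (B, L, C) -> (B*Lout, filterWidth*C); row r = b + (t-1)*B, column u + (c-1)*fw
im2col <- function(X, fw) {
  d <- dim(X)
  .im2colC(X, d[1], d[2], d[3], fw)
}

convForward <- function(layer, X, train = FALSE) {
  d <- dim(X)
  if (length(d) != 3L || d[3] != layer$inChannels)
    stop("conv1d: input must be (batch, length, ", layer$inChannels,
         ") array, got dims ", paste(d, collapse = "x"))
  fw <- layer$filterWidth
  if (d[2] < fw) stop("conv1d: input length ", d[2], " shorter than filter ", fw)
  XC <- im2col(X, fw)
  Z <- XC %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  A <- if (layer$activation == "relu") pmax(Z, 0) else Z
  Lout <- d[2] - fw + 1L
  dim(A) <- c(d[1], Lout, layer$nFilters)
  list(out = A, cache = list(XC = XC, mask = Z > 0, dims = d, Lout = Lout))
}

convBackward <- function(layer, cache, dOut) {
  d <- cache$dims
  fw <- layer$filterWidth
  Lout <- cache$Lout
  dZ <- dOut
  dim(dZ) <- c(d[1] * Lout, layer$nFilters)
  if (layer$activation == "relu") dZ <- dZ * cache$mask
  dW <- crossprod(cache$XC, dZ)
  db <- colSums(dZ)
  dXC <- tcrossprod(dZ, layer$W)
  dX <- .col2imC(dXC, d[1], d[2], d[3], fw)
  list(grads = list(W = dW, b = db), dX = dX)
}

## ---- maxpool ------------------------------------------------------------

poolForward <- function(layer, X, train = FALSE) {
  d <- dim(X)
  p <- layer$poolWidth
  if (d[2] %/% p < 1L) stop("maxpool: input length ", d[2], " shorter than pool ", p)
  fw <- .maxpoolFwdC(X, d[1], d[2], d[3], p)
  list(out = fw$out, cache = list(argm = fw$argm, dims = d))
}

poolBackward <- function(layer, cache, dOut) {
  d <- cache$dims
  dX <- .maxpoolBwdC(dOut, cache$argm, d[1], d[2], d[3], layer$poolWidth)
  list(grads = list(), dX = dX)
}

## ---- lstm ---------------------------------------------------------------

lstmForward <- function(layer, X, train = FALSE) {
  d <- dim(X)
  if (length(d) != 3L || d[3] != layer$inSize)
    stop("lstm: input must be (batch, time, ", layer$inSize, ") array")
  B <- d[1]; Tn <- d[2]; H <- layer$units
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  steps <- vector("list", Tn)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], B, layer$inSize)
    G <- Xt %*% layer$Wx + h %*% layer$Wh
    G <- G + rep(layer$b, each = B)
    gi <- stableSigmoid(G[, i1, drop = FALSE])
    gf <- stableSigmoid(G[, i2, drop = FALSE])
    gg <- tanh(G[, i3, drop = FALSE])
    go <- stableSigmoid(G[, i4, drop = FALSE])
    cPrev <- cc
    cc <- gf * cPrev + gi * gg
    tc <- tanh(cc)
    hPrev <- h
    h <- go * tc
    steps[[t]] <- list(Xt = Xt, gi = gi, gf = gf, gg = gg, go = go,
                       cPrev = cPrev, tc = tc, hPrev = hPrev)
  }
  list(out = h, cache = list(steps = steps, dims = d))
}

lstmBackward <- function(layer, cache, dOut) {
  d <- cache$dims
  B <- d[1]; Tn <- d[2]; H <- layer$units
  dWx <- array(0, dim(layer$Wx))
  dWh <- array(0, dim(layer$Wh))
  db <- numeric(4 * H)
  dX <- array(0, d)
  dH <- dOut
  dC <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dGo <- dH * s$tc * s$go * (1 - s$go)
    dC <- dC + dH * s$go * (1 - s$tc^2)
    dGi <- dC * s$gg * s$gi * (1 - s$gi)
    dGf <- dC * s$cPrev * s$gf * (1 - s$gf)
    dGg <- dC * s$gi * (1 - s$gg^2)
    dG <- cbind(dGi, dGf, dGg, dGo)
    dWx <- dWx + crossprod(s$Xt, dG)
    dWh <- dWh + crossprod(s$hPrev, dG)
    db <- db + colSums(dG)
    dX[, t, ] <- tcrossprod(dG, layer$Wx)
    dH <- tcrossprod(dG, layer$Wh)
    dC <- dC * s$gf
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

## ---- dense --------------------------------------------------------------

denseForward <- function(layer, X, train = FALSE) {
  if (!is.matrix(X)) stop("dense: input must be a matrix")
  if (ncol(X) != layer$inSize)
    stop("dense: expected ", layer$inSize, " inputs, got ", ncol(X))
  Z <- X %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  A <- switch(layer$activation,
              relu = pmax(Z, 0),
              tanh = tanh(Z),
              linear = Z,
              stop("unknown activation: ", layer$activation))
  mask <- NULL
  if (train && layer$dropout > 0) {
    keep <- 1 - layer$dropout
    mask <- matrix((stats::runif(length(A)) < keep) / keep, nrow(A), ncol(A))
    A <- A * mask
  }
  list(out = A, cache = list(X = X, Z = Z, A0 = A, mask = mask))
}

denseBackward <- function(layer, cache, dOut) {
  dA <- dOut
  if (!is.null(cache$mask)) dA <- dA * cache$mask
  dZ <- switch(layer$activation,
               relu = dA * (cache$Z > 0),
               tanh = dA * (1 - tanh(cache$Z)^2),
               linear = dA)
  list(grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)),
       dX = tcrossprod(dZ, layer$W))
}

## ---- stack --------------------------------------------------------------

layerForward <- function(layer, X, train) {
  switch(layer$type,
         conv1d = convForward(layer, X, train),
         maxpool = poolForward(layer, X, train),
         lstm = lstmForward(layer, X, train),
         dense = denseForward(layer, X, train))
}

layerBackward <- function(layer, cache, dOut) {
  switch(layer$type,
         conv1d = convBackward(layer, cache, dOut),
         maxpool = poolBackward(layer, cache, dOut),
         lstm = lstmBackward(layer, cache, dOut),
         dense = denseBackward(layer, cache, dOut))
}

nnForward <- function(net, X, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- layerForward(net$layers[[i]], X, train)
    X <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

# dOut: gradient w.r.t. the stack output. Returns per-layer parameter
# gradients plus the gradient w.r.t. the stack input (needed by integrated
# gradients). stopAt > 1 truncates backpropagation below that layer (used
# when all lower layers are frozen); dX is then NULL.
nnBackward <- function(net, caches, dOut, stopAt = 1L) {
  n <- length(net$layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    if (i < stopAt) break
    bw <- layerBackward(net$layers[[i]], caches[[i]], dOut)
    grads[[i]] <- bw$grads
    dOut <- bw$dX
  }
  list(grads = grads, dX = if (stopAt == 1L) dOut else NULL)
}

## ---- parameter plumbing -------------------------------------------------

paramNames <- function(layer) {
  switch(layer$type,
         conv1d = c("W", "b"),
         dense = c("W", "b"),
         lstm = c("Wx", "Wh", "b"),
         maxpool = character(0))
}

# flat named list of all parameter arrays, for freeze audits and checkpoints
nnParams <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    for (p in paramNames(net$layers[[i]]))
      out[[paste0("layer", i, ".", p)]] <- net$layers[[i]][[p]]
  }
  out
}

nnSetFrozen <- function(net, frozen) {
  stopifnot(length(frozen) == length(net$layers))
  for (i in seq_along(net$layers)) net$layers[[i]]$frozen <- frozen[i]
  net
}

nnFrozen <- function(net) vapply(net$layers, function(l) isTRUE(l$frozen), logical(1))

## ---- Adam ---------------------------------------------------------------

adamInit <- function(net) {
  st <- list(t = 0L, layers = vector("list", length(net$layers)))
  for (i in seq_along(net$layers)) {
    ps <- paramNames(net$layers[[i]])
    st$layers[[i]] <- lapply(stats::setNames(ps, ps), function(p) {
      arr <- net$layers[[i]][[p]]
      list(m = array(0, dim(arr) %||% length(arr)), v = array(0, dim(arr) %||% length(arr)))
    })
  }
  st
}

adamStep <- function(net, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    if (isTRUE(layer$frozen) || is.null(grads[[i]])) next
    for (p in paramNames(layer)) {
      g <- grads[[i]][[p]]
      s <- state$layers[[i]][[p]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      net$layers[[i]][[p]] <- layer[[p]] - lr * (s$m / c1) / (sqrt(s$v / c2) + eps)
      state$layers[[i]][[p]] <- s
      layer <- net$layers[[i]]
    }
  }
  list(net = net, state = state)
}

adamVecInit <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamVecStep <- function(x, g, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
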