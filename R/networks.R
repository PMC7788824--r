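#' Sequence sub-network configuration
#'
#' The published architecture uses 240 filters of 20 bp, 15 bp non-overlapping
#' max-pooling, a 32-unit unidirectional LSTM and two ReLU dense layers with
#' dropout, ending in a single tanh node. The dense widths and dropout rate
#' were grid-searched in the original work without the winners being printed;
#' the defaults here are declared choices. The "tiny" preset (32 filters,
#' dense 32/16) is a desk-scale architecture for simulation studies and tests.
#'
#' @param nFilters Convolutional filters (default 240).
#' @param filterWidth Filter width in bp (default 20).
#' @param poolWidth Max-pool width in positions (non-overlapping; a final
#'   partial pool is dropped). Default 15 for the published architecture and
#'   96 for the tiny preset: with few training sites, a short pooled sequence
#'   (five LSTM steps) generalizes where a long one lets the recurrent stage
#'   memorize position-specific patterns.
#' @param lstmUnits LSTM output size (default 32).
#' @param denseSizes Widths of the two ReLU dense layers (default c(512, 256)).
#' @param dropout Dropout rate after each ReLU dense layer (default 0.5 for
#'   the published architecture, 0.2 for the tiny preset whose small dense
#'   layers need less regularization).
#' @param windowWidth Input window width in bp (default 500).
#' @param preset "published" or "tiny".
#' @return A config list.
#' @export
seqSubnetConfig <- function(preset = c("published", "tiny"),
                            nFilters = NULL, filterWidth = 20L,
                            poolWidth = NULL, lstmUnits = 32L,
                            denseSizes = NULL, dropout = NULL,
                            windowWidth = 500L) {
  preset <- match.arg(preset)
  if (is.null(nFilters)) nFilters <- if (preset == "tiny") 32L else 240L
  if (is.null(denseSizes))
    denseSizes <- if (preset == "tiny") c(32L, 16L) else c(512L, 256L)
  if (is.null(dropout)) dropout <- if (preset == "tiny") 0.2 else 0.5
  if (is.null(poolWidth)) poolWidth <- if (preset == "tiny") 96L else 15L
  cfg <- list(nFilters = as.integer(nFilters),
              filterWidth = as.integer(filterWidth),
              poolWidth = as.integer(poolWidth),
              lstmUnits = as.integer(lstmUnits),
              denseSizes = as.integer(denseSizes),
              dropout = dropout, windowWidth = as.integer(windowWidth))
  stopifnot(all(unlist(cfg[1:4]) > 0), length(cfg$denseSizes) >= 1,
            dropout >= 0, dropout < 1)
  if (cfg$windowWidth - cfg$filterWidth + 1L < cfg$poolWidth)
    stop("config inconsistent with input length: nothing left after pooling")
  cfg
}

#' Chromatin sub-network configuration
#'
#' Convolutional filters span exactly two input bins; the conv output feeds an
#' LSTM, one dense layer, and a single tanh node.
#'
#' @param nFilters Convolutional filters (default 16).
#' @param lstmUnits LSTM output size (default 8).
#' @param denseSize Width of the single dense layer (default 8).
#' @param nBins Input bins per window (default 10).
#' @return A config list.
#' @export
chrSubnetConfig <- function(nFilters = 16L, lstmUnits = 8L, denseSize = 8L,
                            nBins = 10L) {
  cfg <- list(nFilters = as.integer(nFilters), filterSpanBins = 2L,
              lstmUnits = as.integer(lstmUnits),
              denseSize = as.integer(denseSize), nBins = as.integer(nBins))
  stopifnot(all(unlist(cfg) > 0))
  cfg
}

#' Build the sequence sub-network trunk
#'
#' Pipeline: 1-D convolution (valid padding, ReLU) over the one-hot sequence
#' with the four bases as channels, non-overlapping max-pooling, a
#' unidirectional LSTM whose final hidden state feeds the dense stack
#' (ReLU + dropout), and a single tanh-activated node, so the trunk output
#' phiS lies in (-1, 1). Weights are initialized from the current RNG state.
#'
#' @param config From \code{\link{seqSubnetConfig}}.
#' @return A layer stack (internal representation).
#' @export
buildSeqSubnetwork <- function(config = seqSubnetConfig()) {
  layers <- list(
    nnConv1d(4L, config$nFilters, config$filterWidth, activation = "relu"),
    nnMaxPool(config$poolWidth),
    nnLSTM(config$nFilters, config$lstmUnits))
  inSize <- config$lstmUnits
  for (w in config$denseSizes) {
    layers <- c(layers, list(nnDense(inSize, w, "relu", dropout = config$dropout)))
    inSize <- w
  }
  layers <- c(layers, list(nnDense(inSize, 1L, "tanh")))
  list(layers = layers, config = config)
}

#' Build the chromatin sub-network trunk
#'
#' Convolution over the bin axis (span 2 bins, the k tracks as channels,
#' ReLU), LSTM, one ReLU dense layer, and a single tanh node; output phiC in
#' (-1, 1). Accepts any k >= 1 (k = 1 is the ATAC-only mode).
#'
#' @param config From \code{\link{chrSubnetConfig}}.
#' @param kTracks Number of chromatin tracks.
#' @return A layer stack.
#' @export
buildChrSubnetwork <- function(config = chrSubnetConfig(), kTracks = 1L) {
  stopifnot(kTracks >= 1)
  layers <- list(
    nnConv1d(as.integer(kTracks), config$nFilters, config$filterSpanBins,
             activation = "relu"),
    nnLSTM(config$nFilters, config$lstmUnits),
    nnDense(config$lstmUnits, config$denseSize, "relu"),
    nnDense(config$denseSize, 1L, "tanh"))
  list(layers = layers, config = config, kTracks = as.integer(kTracks))
}

#' Build a sequence-only baseline model
#'
#' The sequence trunk followed by a scalar sigmoid head:
#' P(bound) = sigmoid(w * phiS + b). The trunk is identical to the bimodal
#' sequence sub-network, so weights transfer without reshaping.
#'
#' @param config From \code{\link{seqSubnetConfig}}.
#' @param seed Optional seed for weight initialization.
#' @return A \linkS4class{SequenceModel}.
#' @export
buildSequenceOnly <- function(config = seqSubnetConfig(), seed = NULL) {
  withSeed(seed, {
    trunk <- buildSeqSubnetwork(config)
    methods::new("SequenceModel", trunk = trunk,
                 head = c(w = 1, b = 0), config = config)
  })
}

#' Build the additive bimodal model
#'
#' Combines a sequence trunk and a chromatin trunk through three scalar
#' combiner weights: logit(y) = b0 + bS * phiS + bC * phiC. The combiner has
#' no hidden layer, so the latent decomposition into seqscore and chromscore
#' is exact.
#'
#' @param seqTrunk From \code{\link{buildSeqSubnetwork}} (or a transferred
#'   trunk).
#' @param chrTrunk From \code{\link{buildChrSubnetwork}}.
#' @param beta Initial combiner weights c(b0, bS, bC).
#' @return A \linkS4class{BimodalModel}.
#' @export
buildBimodal <- function(seqTrunk, chrTrunk, beta = c(b0 = 0, bS = 1, bC = 1)) {
  stopifnot(length(beta) == 3)
  methods::new("BimodalModel", seqTrunk = seqTrunk,
               chrTrunk = chrTrunk,
               beta = stats::setNames(as.numeric(beta), c("b0", "bS", "bC")),
               kTracks = as.integer(chrTrunk$kTracks %||% 1L),
               config = list(seq = seqTrunk$config, chr = chrTrunk$config))
}

#' Binary cross-entropy loss
#'
#' J = -(1/N) sum_i [ y_i log(yhat_i) + (1 - y_i) log(1 - yhat_i) ], with
#' predictions clipped into (eps, 1 - eps).
#'
#' @param y Labels in {0, 1}.
#' @param yhat Predicted probabilities.
#' @param eps Clipping constant (default 1e-7).
#' @return The mean loss (a single number).
#' @examples
#' binaryCrossEntropy(1, 0.5)  # log(2)
#' @export
binaryCrossEntropy <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- forward passes ------------------------------------------------------

# run a trunk over a 3-D input in inference chunks to bound memory
trunkScores <- function(trunk, X, train = FALSE, chunk = 512L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- scalarOut(nnForward(trunk, X[s:e, , , drop = FALSE],
                                    train = train)$out)[, 1]
  }
  out
}

checkSeqInput <- function(trunk, X) {
  w <- trunk$config$windowWidth %||% 500L
  d <- dim(X)
  if (length(d) != 3L || d[2] != w || d[3] != 4L)
    stop("sequence input must be (batch, ", w, ", 4); got dims ",
         paste(d, collapse = "x"))
}

#' @rdname predictProb
#' @export
setMethod("seqActivations", "SequenceModel", function(model, newdata, ...) {
  X <- if (methods::is(newdata, "ChromDataset")) seqOneHot(newdata) else newdata
  checkSeqInput(model@trunk, X)
  trunkScores(model@trunk, X)
})

#' @rdname predictProb
#' @export
setMethod("seqActivations", "BimodalModel", function(model, newdata, ...) {
  X <- if (methods::is(newdata, "ChromDataset")) seqOneHot(newdata) else newdata
  checkSeqInput(model@seqTrunk, X)
  trunkScores(model@seqTrunk, X)
})

#' @rdname predictProb
#' @export
setMethod("chromActivations", "BimodalModel", function(model, newdata, ...) {
  X <- if (methods::is(newdata, "ChromDataset")) chromSignal(newdata) else newdata
  if (dim(X)[3] != model@kTracks)
    stop("chromatin input has ", dim(X)[3], " tracks; model expects ",
         model@kTracks)
  trunkScores(model@chrTrunk, X)
})

#' @rdname predictProb
#' @export
setMethod("predictProb", "SequenceModel", function(model, newdata, ...) {
  if (methods::is(newdata, "ChromDataset") == FALSE && length(dim(newdata)) != 3)
    stop("sequence-only model scores sequence input only")
  phi <- seqActivations(model, newdata)
  stableSigmoid(model@head[["w"]] * phi + model@head[["b"]])
})

#' @rdname predictProb
#' @export
setMethod("predictProb", "BimodalModel", function(model, newdata, ...) {
  if (!methods::is(newdata, "ChromDataset"))
    stop("bimodal model scores a ChromDataset")
  phiS <- seqActivations(model, newdata)
  phiC <- chromActivations(model, newdata)
  b <- model@beta
  stableSigmoid(b[["b0"]] + b[["bS"]] * phiS + b[["bC"]] * phiC)
})

setMethod("show", "SequenceModel", function(object) {
  cfg <- object@config
  cat("SequenceModel:", cfg$nFilters, "x", cfg$filterWidth, "bp conv ->",
      "pool", cfg$poolWidth, "-> LSTM", cfg$lstmUnits, "-> dense",
      paste(cfg$denseSizes, collapse = "/"), "-> tanh -> sigmoid head\n")
})

setMethod("show", "BimodalModel", function(object) {
  b <- object@beta
  cat("BimodalModel: logit(y) =", sprintf("%.3f", b[["b0"]]), "+",
      sprintf("%.3f", b[["bS"]]), "* phiS +", sprintf("%.3f", b[["bC"]]),
      "* phiC  (k =", object@kTracks, "tracks)\n")
})

#' Number of trainable parameters of a layer stack
#' @param trunk A layer stack.
#' @keywords internal
trunkNParams <- function(trunk) {
  sum(vapply(nnParams(trunk), length, integer(1)))
}
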