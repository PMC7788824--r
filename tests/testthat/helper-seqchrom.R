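# Shared fixtures for the test suite. Heavy artifacts (simulations, trained
# models) are built once per session and cached in this environment so the
# acceptance blocks can share them.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# a small but non-degenerate simulated study for fast functional tests:
# tiny preset geometry shrunk to 3 x 60 kb, coarse training tiling
quickSim <- function() cached("quickSim", {
  simulateDataset(simConfig("tiny", chromLength = 60000L), seed = 401L)
})

quickSplit <- function() cached("quickSplit", {
  simSplit(quickSim(), testChrom = "chrS1", valChrom = "chrS2",
           trainStep = 250L)
})

# architecture small enough that one training epoch takes seconds
quickSeqConfig <- function() seqSubnetConfig("tiny", nFilters = 8L,
                                             denseSizes = c(8L, 4L),
                                             lstmUnits = 8L)

quickChrConfig <- function() chrSubnetConfig(nFilters = 4L, lstmUnits = 4L,
                                             denseSize = 4L)

quickSeqRun <- function() cached("quickSeqRun", {
  sp <- quickSplit()
  trainSequenceNetwork(sp$train, sp$val, config = quickSeqConfig(),
                       sampler = "random", seed = 401L, epochs = 2L,
                       batchSize = 32L, posFrac = 0.5, lr = 3e-3)
})

quickBimRun <- function() cached("quickBimRun", {
  sp <- quickSplit()
  transferAndTrainBimodal(quickSeqRun(), sp$train, sp$val,
                          chrConfig = quickChrConfig(), seed = 401L,
                          epochs = 2L, batchSize = 32L, posFrac = 0.5,
                          lr = 3e-3)
})

# hand-built ChromDataset with full control over labels and accessibility;
# sequence/chromatin content is arbitrary (samplers never look at it)
toyDataset <- function(labels, accessible, width = 20L, nBins = 10L,
                       k = 1L, chrom = rep("chrT1", length(labels))) {
  n <- length(labels)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = seq_len(n) * width + 1L, width = width))
  set.seed(7)
  methods::new("ChromDataset",
               rowRanges = gr,
               seqCode = matrix(sample(1:4, n * width, replace = TRUE),
                                n, width),
               chromFeat = array(stats::runif(n * nBins * k), c(n, nBins, k)),
               label = factor(labels,
                              levels = c("unbound", "bound", "ambiguous")),
               accessible = accessible,
               trackNames = paste0("track", seq_len(k)),
               normTotal = 1)
}

# a single-filter, full-width linear convolution trunk: F(x) = <W, x> + b,
# the analytically tractable "linear head" for the IG axioms
linearSeqModel <- function(L = 30L, seed = 5L, w = 1, b = 0) {
  set.seed(seed)
  conv <- seqchrom:::nnConv1d(4L, 1L, L, activation = "linear")
  trunk <- list(layers = list(conv), config = list(windowWidth = L))
  methods::new("SequenceModel", trunk = trunk,
               head = c(w = w, b = b),
               config = list(windowWidth = L))
}

# the (L x 4) gradient matrix of a linearSeqModel's head:
# grad[u, c] = w * W[u + (c-1) * L]  (im2col column layout)
linearModelGrad <- function(model) {
  L <- model@config$windowWidth
  W <- model@trunk$layers[[1]]$W[, 1]
  model@head[["w"]] * matrix(W, L, 4)
}

# adjusted Rand index between two labelings
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxIdx <- (ai + bj) / 2
  if (maxIdx == expected) return(1)
  (nij - expected) / (maxIdx - expected)
}
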