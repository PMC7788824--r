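# Batch samplers and the two-stage training protocol.
#
# The sequence-only network is trained with accessibility-controlled batches
# so it cannot learn accessibility-correlated sequence as a confound; the
# bimodal network then receives the sequence trunk by weight transfer (lower
# layers frozen) and is trained with plain imbalanced random batches.

trainableIdx <- function(ds) {
  lab <- bindingLabels(ds)
  if (any(is.na(lab))) stop("dataset contains unlabeled windows")
  list(pos = which(lab == "bound"), neg = which(lab == "unbound"))
}

newBatchPlan <- function(batches, type, batchSize, posFrac, seed) {
  structure(list(batches = batches, type = type, batchSize = batchSize,
                 posFrac = posFrac, seed = seed), class = "BatchPlan")
}

#' @export
print.BatchPlan <- function(x, ...) {
  cat("BatchPlan (", x$type, "): ", length(x$batches), " batches of ",
      x$batchSize, " (", round(100 * x$posFrac), "% positives)\n", sep = "")
  invisible(x)
}

#' Accessibility-matched batch sampler
#'
#' Every emitted batch is homogeneous in prior accessibility: all its bound
#' and unbound members are either accessible or all inaccessible. Positives
#' are consumed without replacement once per epoch within each stratum;
#' negatives are subsampled from the same stratum. Ambiguous windows must
#' already be excluded (they are, in any \code{\link{chromosomeSplit}} part).
#'
#' @param dataset Training \linkS4class{ChromDataset} with accessibility set.
#' @param batchSize Windows per batch (default 128).
#' @param posFrac Fraction of positives per batch (default 0.2, i.e. 1:4).
#' @param seed Integer seed; the same seed reproduces the identical plan.
#' @return A BatchPlan: list of batches, each with window ids \code{pos},
#'   \code{neg} and its \code{accessibility} stratum.
#' @export
matchedBatchSampler <- function(dataset, batchSize = 128L, posFrac = 0.2,
                                seed = 1L) {
  acc <- accessibility(dataset)
  if (any(is.na(acc))) stop("accessibility flags must be assigned")
  idx <- trainableIdx(dataset)
  strata <- list(accessible = which(acc), inaccessible = which(!acc))
  for (s in names(strata)) {
    if (!length(intersect(idx$pos, strata[[s]])))
      stop("stratum '", s, "' has no bound windows; ",
           "use relaxedBatchSampler for TFs with one-sided accessibility")
    if (!length(intersect(idx$neg, strata[[s]])))
      stop("stratum '", s, "' has no unbound windows")
  }
  nPos <- max(1L, round(batchSize * posFrac))
  nNeg <- batchSize - nPos
  withSeed(seed, {
    batches <- list()
    for (s in names(strata)) {
      pos <- sample(intersect(idx$pos, strata[[s]]))
      neg <- intersect(idx$neg, strata[[s]])
      nb <- ceiling(length(pos) / nPos)
      for (b in seq_len(nb)) {
        bp <- pos[((b - 1L) * nPos + 1L):min(b * nPos, length(pos))]
        bn <- sample(neg, min(nNeg, length(neg)))
        batches[[length(batches) + 1L]] <-
          list(pos = bp, neg = bn, accessibility = s)
      }
    }
    batches <- batches[sample(length(batches))]
    newBatchPlan(batches, "matched", batchSize, posFrac, seed)
  })
}

#' Relaxed (accessibility-frequency-matched) batch sampler
#'
#' For factors binding almost exclusively accessible chromatin, strict
#' stratification starves batches of inaccessible positives. This sampler
#' instead matches the accessible fraction of the negatives to the realized
#' accessible fraction of each batch's positives, to within \code{tol}.
#'
#' @inheritParams matchedBatchSampler
#' @param tol Maximum allowed difference between the accessible fractions of
#'   positives and negatives within a batch (default 0.05).
#' @return A BatchPlan.
#' @export
relaxedBatchSampler <- function(dataset, batchSize = 128L, posFrac = 0.2,
                                tol = 0.05, seed = 1L) {
  acc <- accessibility(dataset)
  if (any(is.na(acc))) stop("accessibility flags must be assigned")
  idx <- trainableIdx(dataset)
  if (!length(idx$pos) || !length(idx$neg))
    stop("training data must contain bound and unbound windows")
  nPos <- max(1L, round(batchSize * posFrac))
  nNeg <- batchSize - nPos
  negAcc <- intersect(idx$neg, which(acc))
  negInacc <- intersect(idx$neg, which(!acc))
  withSeed(seed, {
    pos <- sample(idx$pos)
    nb <- ceiling(length(pos) / nPos)
    batches <- vector("list", nb)
    for (b in seq_len(nb)) {
      bp <- pos[((b - 1L) * nPos + 1L):min(b * nPos, length(pos))]
      fracA <- mean(acc[bp])
      nA <- round(fracA * nNeg)
      nI <- nNeg - nA
      if (nA > length(negAcc) || nI > length(negInacc))
        stop("relaxed sampling infeasible: not enough ",
             if (nA > length(negAcc)) "accessible" else "inaccessible",
             " unbound windows to match the positives' fraction")
      bn <- c(if (nA) sample(negAcc, nA) else integer(0),
              if (nI) sample(negInacc, nI) else integer(0))
      achieved <- abs(mean(acc[bp]) - mean(acc[bn]))
      if (achieved > tol + 1e-12)
        stop("relaxed sampling cannot meet tol = ", tol,
             " with batch size ", batchSize, " (achieved ",
             signif(achieved, 3), "); increase tol or batch size")
      batches[[b]] <- list(pos = bp, neg = bn,
                           accessibility = sprintf("mixed(%.2f)", fracA))
    }
    newBatchPlan(batches, "relaxed", batchSize, posFrac, seed)
  })
}

#' Plain imbalanced random sampler
#'
#' Positives without replacement per epoch; negatives drawn at random across
#' the genome with no accessibility constraint -- the regime used for bimodal
#' training after weight transfer.
#'
#' @inheritParams matchedBatchSampler
#' @return A BatchPlan.
#' @export
randomBatchSampler <- function(dataset, batchSize = 128L, posFrac = 0.2,
                               seed = 1L) {
  idx <- trainableIdx(dataset)
  if (!length(idx$pos) || !length(idx$neg))
    stop("training data must contain bound and unbound windows")
  nPos <- max(1L, round(batchSize * posFrac))
  nNeg <- batchSize - nPos
  withSeed(seed, {
    pos <- sample(idx$pos)
    nb <- ceiling(length(pos) / nPos)
    batches <- vector("list", nb)
    for (b in seq_len(nb)) {
      bp <- pos[((b - 1L) * nPos + 1L):min(b * nPos, length(pos))]
      batches[[b]] <- list(pos = bp,
                           neg = sample(idx$neg, min(nNeg, length(idx$neg))),
                           accessibility = "unconstrained")
    }
    newBatchPlan(batches, "random", batchSize, posFrac, seed)
  })
}

#' Choose matched vs relaxed sampling
#'
#' Matched sampling needs enough bound windows in previously inaccessible
#' chromatin. If the fraction of bound windows that are inaccessible is at
#' least \code{fracThreshold} (default 0.10; the boundary itself selects
#' matched), the matched sampler is chosen, otherwise the relaxed one.
#'
#' @param dataset Labeled dataset with accessibility flags.
#' @param fracThreshold Switch point (default 0.10).
#' @return "matched" or "relaxed".
#' @export
selectSampler <- function(dataset, fracThreshold = 0.10) {
  acc <- accessibility(dataset)
  if (any(is.na(acc))) stop("accessibility flags must be assigned")
  bound <- bindingLabels(dataset) == "bound"
  if (!any(bound)) stop("no bound windows")
  frac <- mean(!acc[bound])
  if (frac >= fracThreshold) "matched" else "relaxed"
}

samplerByName <- function(name) {
  switch(name,
         matched = matchedBatchSampler,
         relaxed = relaxedBatchSampler,
         random = randomBatchSampler,
         stop("unknown sampler: ", name))
}

# one-hot + label extraction for a batch
batchTensors <- function(dataset, batch) {
  ids <- c(batch$pos, batch$neg)
  list(ids = ids,
       X = seqOneHot(dataset, ids),
       C = chromSignal(dataset, ids),
       y = as.numeric(bindingLabels(dataset)[ids] == "bound"))
}

evalAuprc <- function(scores, labels) {
  if (!any(labels == 1)) return(NA_real_)
  auprc(prCurve(scores, labels))
}

#' Train the sequence-only network
#'
#' Minimizes binary cross-entropy with Adam under the chosen batch sampler.
#' After each epoch the model is scored on the validation chromosome and the
#' checkpoint with the best validation auPRC is retained.
#'
#' @param train,val Training and validation \linkS4class{ChromDataset}s
#'   (ambiguous windows excluded, accessibility assigned).
#' @param config Architecture from \code{\link{seqSubnetConfig}}.
#' @param sampler "auto" (via \code{\link{selectSampler}}), "matched",
#'   "relaxed", or "random".
#' @param seed Integer seed controlling initialization, sampling and dropout.
#' @param epochs,batchSize,posFrac,lr Training hyper-parameters.
#' @return A \linkS4class{TrainingRun}.
#' @export
trainSequenceNetwork <- function(train, val, config = seqSubnetConfig("tiny"),
                                 sampler = "auto", seed = 1L, epochs = 15L,
                                 batchSize = 128L, posFrac = 0.2, lr = 1e-3) {
  if (nWindows(train) == 0) stop("empty training set")
  if (sampler == "auto") sampler <- selectSampler(train)
  sampleFun <- samplerByName(sampler)
  withSeed(seed, {
    model <- buildSequenceOnly(config)
    trunk <- model@trunk
    head <- model@head
    adamT <- adamInit(trunk)
    adamH <- adamVecInit(2L)
    history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                          valAuprc = numeric(0))
    best <- list(auprc = -Inf, trunk = trunk, head = head, epoch = 0L)
    for (e in seq_len(epochs)) {
      plan <- sampleFun(train, batchSize = batchSize, posFrac = posFrac,
                        seed = deriveSeed(seed, e))
      losses <- numeric(length(plan$batches))
      for (bi in seq_along(plan$batches)) {
        bt <- batchTensors(train, plan$batches[[bi]])
        fw <- nnForward(trunk, bt$X, train = TRUE)
        phi <- fw$out[, 1]
        p <- stableSigmoid(head[["w"]] * phi + head[["b"]])
        losses[bi] <- binaryCrossEntropy(bt$y, p)
        if (!is.finite(losses[bi]))
          stop("divergent loss at epoch ", e, ", batch ", bi,
               " (loss = ", losses[bi], "); lower the learning rate")
        dlogit <- (p - bt$y) / length(bt$y)
        gHead <- c(sum(dlogit * phi), sum(dlogit))
        bw <- nnBackward(trunk, fw$caches,
                         matrix(dlogit * head[["w"]], ncol = 1))
        up <- adamStep(trunk, bw$grads, adamT, lr = lr)
        trunk <- up$net; adamT <- up$state
        uh <- adamVecStep(unname(head), gHead, adamH, lr = lr)
        head <- stats::setNames(uh$x, c("w", "b")); adamH <- uh$state
      }
      vm <- methods::new("SequenceModel", trunk = trunk, head = head,
                         config = config)
      va <- evalAuprc(predictProb(vm, val),
                      as.numeric(bindingLabels(val) == "bound"))
      history <- rbind(history, data.frame(epoch = e,
                                           trainLoss = mean(losses),
                                           valAuprc = va))
      if (is.finite(va) && va > best$auprc)
        best <- list(auprc = va, trunk = trunk, head = head, epoch = e)
    }
    methods::new("TrainingRun", mode = "sequence_only",
                 seed = as.integer(seed), history = history,
                 model = methods::new("SequenceModel", trunk = best$trunk,
                                      head = best$head, config = config),
                 bestEpoch = best$epoch,
                 config = list(sampler = sampler, epochs = epochs,
                               batchSize = batchSize, posFrac = posFrac,
                               lr = lr))
  })
}

# frozen-layer pattern for a transferred sequence trunk:
# conv, (pool), lstm and all dense layers except the final dense + tanh head
# are frozen; fixedDense freezes the whole trunk.
seqFreezePattern <- function(trunk, fixedDense = FALSE,
                             freezeFirstDense = TRUE) {
  types <- vapply(trunk$layers, `[[`, character(1), "type")
  denseIdx <- which(types == "dense")
  frozen <- rep(TRUE, length(types))
  if (!fixedDense) {
    trainable <- utils::tail(denseIdx, 2L)  # final dense + tanh node
    if (!freezeFirstDense)
      trainable <- denseIdx
    frozen[trainable] <- FALSE
  }
  frozen
}

#' Transfer the sequence trunk and train the bimodal model
#'
#' Copies the trained sequence-only trunk into the bimodal model's sequence
#' sub-network, freezes its convolutional, LSTM and lower dense layers (only
#' the final dense layer and the tanh node remain trainable; with
#' \code{fixedDense = TRUE} the whole trunk is frozen -- the
#' fixed-dense control), then trains the chromatin sub-network and the three
#' combiner weights on imbalanced random batches. The combiner is warm-started
#' at the donor solution (bC = 0), and the untrained transfer point competes
#' in best-epoch selection, so the returned model only departs from the
#' sequence-only solution when chromatin improves validation auPRC.
#'
#' With the default \code{selection = "oneSE"}, a trained checkpoint replaces
#' the warm-start solution only if its validation auPRC exceeds the donor's
#' by more than one bootstrap standard error of that estimate (the classical
#' one-standard-error rule). On small validation sets, raw argmax selection
#' can latch onto chance improvements produced by a chromatin trunk that is
#' fitting noise; the margin makes "no better than the sequence-only model"
#' the default outcome unless chromatin helps beyond selection noise.
#' \code{selection = "best"} restores plain argmax over all checkpoints
#' (including the warm start).
#'
#' @param seqRun A sequence-only \linkS4class{TrainingRun} (the donor).
#' @param train,val Datasets as in \code{\link{trainSequenceNetwork}}.
#' @param chrConfig Architecture from \code{\link{chrSubnetConfig}}.
#' @param seed,epochs,batchSize,posFrac,lr Training hyper-parameters.
#' @param fixedDense Freeze all sequence-trunk dense layers (control).
#' @param freezeFirstDense Keep the first dense layer frozen (default TRUE;
#'   flag exposed because the boundary between "lower" and "final" dense
#'   layers is a modeling choice).
#' @param selection Checkpoint selection rule: \code{"oneSE"} (default)
#'   requires a trained checkpoint to beat the warm-start validation auPRC
#'   by more than its bootstrap standard error; \code{"best"} is plain
#'   argmax.
#' @return A \linkS4class{TrainingRun} whose model is a
#'   \linkS4class{BimodalModel}. The run's \code{config} additionally
#'   carries \code{finalModel} (the last-epoch model regardless of
#'   selection, for diagnosing the selection rule) and \code{selectionSe}
#'   (the bootstrap standard error used as the margin).
#' @export
transferAndTrainBimodal <- function(seqRun, train, val,
                                    chrConfig = chrSubnetConfig(),
                                    seed = 1L, epochs = 15L, batchSize = 128L,
                                    posFrac = 0.2, lr = 1e-3,
                                    fixedDense = FALSE,
                                    freezeFirstDense = TRUE,
                                    selection = c("oneSE", "best")) {
  selection <- match.arg(selection)
  stopifnot(methods::is(seqRun, "TrainingRun"),
            methods::is(seqRun@model, "SequenceModel"))
  if (nWindows(train) == 0) stop("empty training set")
  donor <- seqRun@model@trunk
  k <- kTracks(train)
  withSeed(seed, {
    seqTrunk <- donor
    frozen <- seqFreezePattern(seqTrunk, fixedDense = fixedDense,
                               freezeFirstDense = freezeFirstDense)
    seqTrunk <- nnSetFrozen(seqTrunk, frozen)
    chrTrunk <- buildChrSubnetwork(chrConfig, kTracks = k)
    # warm start at the transferred solution: with bC = 0 the bimodal model
    # reproduces the donor's predictions exactly, so validation-based
    # checkpointing can only move away from it when chromatin genuinely helps
    beta <- c(b0 = unname(seqRun@model@head[["b"]]),
              bS = unname(seqRun@model@head[["w"]]), bC = 0)
    adamS <- adamInit(seqTrunk)
    adamC <- adamInit(chrTrunk)
    adamB <- adamVecInit(3L)
    mkModel <- function(st, ct, b)
      methods::new("BimodalModel", seqTrunk = st, chrTrunk = ct,
                   beta = b, kTracks = as.integer(k),
                   config = list(seq = seqRun@model@config, chr = chrConfig))
    yVal <- as.numeric(bindingLabels(val) == "bound")
    p0 <- predictProb(mkModel(seqTrunk, chrTrunk, beta), val)
    va0 <- evalAuprc(p0, yVal)
    # bootstrap SE of the warm-start validation auPRC; isolated from the
    # training RNG stream so the trajectory does not depend on the rule
    se0 <- 0
    if (selection == "oneSE" && is.finite(va0)) {
      se0 <- withSeed(deriveSeed(seed, 999983L), {
        stats::sd(vapply(seq_len(200L), function(i) {
          idx <- sample.int(length(yVal), replace = TRUE)
          evalAuprc(p0[idx], yVal[idx])
        }, numeric(1)), na.rm = TRUE)
      })
      if (!is.finite(se0)) se0 <- 0
    }
    bar <- if (is.finite(va0)) va0 + se0 else -Inf
    history <- data.frame(epoch = 0L, trainLoss = NA_real_, valAuprc = va0)
    best <- list(auprc = if (is.finite(va0)) va0 else -Inf,
                 seqTrunk = seqTrunk, chrTrunk = chrTrunk,
                 beta = beta, epoch = 0L)
    for (e in seq_len(epochs)) {
      plan <- randomBatchSampler(train, batchSize = batchSize,
                                 posFrac = posFrac,
                                 seed = deriveSeed(seed, e))
      losses <- numeric(length(plan$batches))
      for (bi in seq_along(plan$batches)) {
        bt <- batchTensors(train, plan$batches[[bi]])
        fwS <- nnForward(seqTrunk, bt$X, train = TRUE)
        fwC <- nnForward(chrTrunk, bt$C, train = TRUE)
        phiS <- fwS$out[, 1]; phiC <- fwC$out[, 1]
        p <- stableSigmoid(beta[["b0"]] + beta[["bS"]] * phiS +
                             beta[["bC"]] * phiC)
        losses[bi] <- binaryCrossEntropy(bt$y, p)
        if (!is.finite(losses[bi]))
          stop("divergent loss at epoch ", e, ", batch ", bi)
        dlogit <- (p - bt$y) / length(bt$y)
        gBeta <- c(sum(dlogit), sum(dlogit * phiS), sum(dlogit * phiC))
        if (!fixedDense) {
          bwS <- nnBackward(seqTrunk, fwS$caches,
                            matrix(dlogit * beta[["bS"]], ncol = 1),
                            stopAt = min(which(!frozen)))
          upS <- adamStep(seqTrunk, bwS$grads, adamS, lr = lr)
          seqTrunk <- upS$net; adamS <- upS$state
        }
        bwC <- nnBackward(chrTrunk, fwC$caches,
                          matrix(dlogit * beta[["bC"]], ncol = 1))
        upC <- adamStep(chrTrunk, bwC$grads, adamC, lr = lr)
        chrTrunk <- upC$net; adamC <- upC$state
        ub <- adamVecStep(unname(beta), gBeta, adamB, lr = lr)
        beta <- stats::setNames(ub$x, c("b0", "bS", "bC")); adamB <- ub$state
      }
      va <- evalAuprc(predictProb(mkModel(seqTrunk, chrTrunk, beta), val),
                      yVal)
      history <- rbind(history, data.frame(epoch = e,
                                           trainLoss = mean(losses),
                                           valAuprc = va))
      if (is.finite(va) && va > max(bar, best$auprc))
        best <- list(auprc = va, seqTrunk = seqTrunk, chrTrunk = chrTrunk,
                     beta = beta, epoch = e)
    }
    methods::new("TrainingRun",
                 mode = if (fixedDense) "fixed_dense_control" else "bimodal",
                 seed = as.integer(seed), history = history,
                 model = mkModel(best$seqTrunk, best$chrTrunk, best$beta),
                 bestEpoch = best$epoch,
                 config = list(sampler = "random", epochs = epochs,
                               batchSize = batchSize, posFrac = posFrac,
                               lr = lr, fixedDense = fixedDense,
                               freezeFirstDense = freezeFirstDense,
                               selection = selection, selectionSe = se0,
                               finalModel = mkModel(seqTrunk, chrTrunk,
                                                    beta)))
  })
}

#' @rdname transferAndTrainBimodal
#' @param ... Passed to \code{\link{transferAndTrainBimodal}}.
#' @export
trainFixedDenseControl <- function(seqRun, train, val, ...) {
  transferAndTrainBimodal(seqRun, train, val, fixedDense = TRUE, ...)
}

#' Chromosome-holdout k-fold training
#'
#' For each held-out test chromosome, trains the sequence-only network and
#' the transferred bimodal network on the remaining chromosomes (validation
#' chromosome fixed across folds) and evaluates both on the held-out tiling.
#'
#' @param trainData Overlapping-window dataset used for training.
#' @param testData Non-overlapping dataset used for validation/test scoring
#'   (default: \code{trainData}).
#' @param testChroms Chromosomes to hold out in turn (default: all except
#'   \code{valChrom}).
#' @param valChrom Validation chromosome.
#' @param seqConfig,chrConfig Architectures.
#' @param seed,epochs,batchSize,posFrac,lr Training hyper-parameters.
#' @param fpr FPR at which recall is reported.
#' @return List with \code{runs} (per fold, the sequence and bimodal
#'   TrainingRuns) and \code{metrics} (one row per fold and mode: auPRC,
#'   recall at fixed FPR, TP, FN).
#' @export
runKfold <- function(trainData, testData = NULL, testChroms = NULL, valChrom,
                     seqConfig = seqSubnetConfig("tiny"),
                     chrConfig = chrSubnetConfig(), seed = 1L, epochs = 15L,
                     batchSize = 128L, posFrac = 0.2, lr = 1e-3, fpr = 0.05) {
  if (is.null(testData)) testData <- trainData
  chroms <- unique(as.character(GenomicRanges::seqnames(windowRanges(trainData))))
  if (is.null(testChroms)) testChroms <- setdiff(chroms, valChrom)
  if (valChrom %in% testChroms)
    stop("test chromosome list must not include the validation chromosome")
  if (length(testChroms) < 1) stop("need at least one test chromosome")
  runs <- list()
  metrics <- list()
  for (fi in seq_along(testChroms)) {
    tc <- testChroms[fi]
    tr <- chromosomeSplit(trainData, tc, valChrom)$train
    te <- chromosomeSplit(testData, tc, valChrom)
    foldSeed <- deriveSeed(seed, fi)
    seqRun <- trainSequenceNetwork(tr, te$val, config = seqConfig,
                                   seed = foldSeed, epochs = epochs,
                                   batchSize = batchSize, posFrac = posFrac,
                                   lr = lr)
    bimRun <- transferAndTrainBimodal(seqRun, tr, te$val,
                                      chrConfig = chrConfig, seed = foldSeed,
                                      epochs = epochs, batchSize = batchSize,
                                      posFrac = posFrac, lr = lr)
    yTest <- as.numeric(bindingLabels(te$test) == "bound")
    for (mode in c("sequence_only", "bimodal")) {
      run <- if (mode == "sequence_only") seqRun else bimRun
      sc <- if (mode == "sequence_only")
        predictProb(run@model, seqOneHot(te$test)) else
          predictProb(run@model, te$test)
      raf <- recallAtFpr(sc, yTest, fpr = fpr)
      metrics[[length(metrics) + 1L]] <- data.frame(
        fold = tc, mode = mode, auprc = evalAuprc(sc, yTest),
        recallAtFpr = raf$recall, tp = raf$tp, fn = raf$fn)
    }
    runs[[tc]] <- list(sequence = seqRun, bimodal = bimRun)
  }
  list(runs = runs, metrics = do.call(rbind, metrics))
}

## ---- TrainingRun methods -------------------------------------------------

#' @rdname TrainingRun-class
#' @export
setMethod("trainedModel", "TrainingRun", function(x) x@model)

#' @rdname TrainingRun-class
#' @export
setMethod("runHistory", "TrainingRun", function(x) x@history)

setMethod("show", "TrainingRun", function(object) {
  cat("TrainingRun (", object@mode, "): ", nrow(object@history),
      " epochs, best validation auPRC ",
      sprintf("%.3f", max(object@history$valAuprc, na.rm = TRUE)),
      " at epoch ", object@bestEpoch, "\n", sep = "")
})

#' Audit a batch plan against a dataset
#'
#' Returns one row per batch with its realized composition: accessible
#' fraction among positives and negatives and the homogeneity of the batch.
#' Used by tests and run manifests to verify the sampler contracts post hoc.
#'
#' @param plan A BatchPlan.
#' @param dataset The dataset it indexes.
#' @return data.frame with columns batch, nPos, nNeg, fracAccPos, fracAccNeg,
#'   homogeneous.
#' @export
auditBatchPlan <- function(plan, dataset) {
  acc <- accessibility(dataset)
  do.call(rbind, lapply(seq_along(plan$batches), function(i) {
    b <- plan$batches[[i]]
    a <- acc[c(b$pos, b$neg)]
    data.frame(batch = i, nPos = length(b$pos), nNeg = length(b$neg),
               fracAccPos = mean(acc[b$pos]), fracAccNeg = mean(acc[b$neg]),
               homogeneous = length(unique(a)) == 1L)
  }))
}
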