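# Sampler contracts and the two-stage transfer protocol on a hand-built
# dataset where every stratum size is known.

mkTrainable <- function(nPosAcc = 6, nPosInacc = 6, nNegAcc = 30,
                        nNegInacc = 30) {
  labels <- rep(c("bound", "bound", "unbound", "unbound"),
                c(nPosAcc, nPosInacc, nNegAcc, nNegInacc))
  acc <- rep(c(TRUE, FALSE, TRUE, FALSE),
             c(nPosAcc, nPosInacc, nNegAcc, nNegInacc))
  toyDataset(labels, acc)
}

test_that("matched batches are accessibility-homogeneous and cover positives", {
  ds <- mkTrainable()
  plan <- matchedBatchSampler(ds, batchSize = 8L, posFrac = 0.25, seed = 5L)
  audit <- auditBatchPlan(plan, ds)
  expect_true(all(audit$homogeneous))
  expect_true(all(audit$fracAccPos %in% c(0, 1)))
  expect_true(all(audit$fracAccPos == audit$fracAccNeg))
  # every positive appears exactly once per epoch
  posSeen <- sort(unlist(lapply(plan$batches, `[[`, "pos")))
  expect_equal(posSeen, which(bindingLabels(ds) == "bound"))
  # negatives come from the same stratum as their batch's positives
  accv <- accessibility(ds)
  for (b in plan$batches)
    expect_equal(length(unique(accv[c(b$pos, b$neg)])), 1L)
})

test_that("matched sampler names the empty stratum and suggests relaxed", {
  ds <- mkTrainable(nPosInacc = 0)
  expect_error(matchedBatchSampler(ds),
               "stratum 'inaccessible' has no bound.*relaxed")
})

test_that("relaxed batches match accessible fractions within tolerance", {
  ds <- mkTrainable(nPosAcc = 19, nPosInacc = 1, nNegAcc = 60, nNegInacc = 60)
  plan <- relaxedBatchSampler(ds, batchSize = 20L, posFrac = 0.2, tol = 0.05,
                              seed = 6L)
  audit <- auditBatchPlan(plan, ds)
  expect_true(all(abs(audit$fracAccPos - audit$fracAccNeg) <= 0.05 + 1e-12))
  posSeen <- sort(unlist(lapply(plan$batches, `[[`, "pos")))
  expect_equal(posSeen, which(bindingLabels(ds) == "bound"))
})

test_that("relaxed sampler errors when matching is infeasible", {
  ds <- mkTrainable(nPosAcc = 10, nPosInacc = 0, nNegAcc = 1, nNegInacc = 60)
  expect_error(relaxedBatchSampler(ds, batchSize = 10L, posFrac = 0.2),
               "infeasible")
})

test_that("random sampler uses every positive once, negatives unconstrained", {
  ds <- mkTrainable()
  plan <- randomBatchSampler(ds, batchSize = 10L, posFrac = 0.3, seed = 7L)
  posSeen <- sort(unlist(lapply(plan$batches, `[[`, "pos")))
  expect_equal(posSeen, which(bindingLabels(ds) == "bound"))
  expect_equal(plan$type, "random")
})

test_that("selectSampler switches exactly at the 10% boundary", {
  # 10 bound windows, 1 inaccessible = exactly 10% -> matched
  at <- mkTrainable(nPosAcc = 9, nPosInacc = 1)
  expect_equal(selectSampler(at), "matched")
  # just below: 19 accessible + 1 inaccessible = 5% -> relaxed
  below <- mkTrainable(nPosAcc = 19, nPosInacc = 1)
  expect_equal(selectSampler(below), "relaxed")
  # just above
  above <- mkTrainable(nPosAcc = 8, nPosInacc = 1)
  expect_equal(selectSampler(above), "matched")
})

test_that("batch plans are reproducible under a seed", {
  ds <- mkTrainable()
  p1 <- matchedBatchSampler(ds, batchSize = 8L, seed = 42L)
  p2 <- matchedBatchSampler(ds, batchSize = 8L, seed = 42L)
  expect_identical(p1$batches, p2$batches)
  p3 <- matchedBatchSampler(ds, batchSize = 8L, seed = 43L)
  expect_false(identical(p1$batches, p3$batches))
})

test_that("training is deterministic under a fixed seed", {
  sp <- quickSplit()
  r1 <- trainSequenceNetwork(sp$train, sp$val, config = quickSeqConfig(),
                             sampler = "random", seed = 77L, epochs = 1L,
                             batchSize = 32L, posFrac = 0.5, lr = 3e-3)
  r2 <- trainSequenceNetwork(sp$train, sp$val, config = quickSeqConfig(),
                             sampler = "random", seed = 77L, epochs = 1L,
                             batchSize = 32L, posFrac = 0.5, lr = 3e-3)
  expect_identical(seqchrom:::nnParams(trainedModel(r1)@trunk),
                   seqchrom:::nnParams(trainedModel(r2)@trunk))
  expect_identical(runHistory(r1), runHistory(r2))
})

test_that("transfer freezes the trunk below the final dense layers", {
  seqRun <- quickSeqRun()
  bimRun <- quickBimRun()
  donor <- seqchrom:::nnParams(trainedModel(seqRun)@trunk)
  # the last-epoch model shows the training effect regardless of which
  # checkpoint the selection rule kept
  after <- seqchrom:::nnParams(bimRun@config$finalModel@seqTrunk)
  # layers: 1 conv, 2 pool, 3 lstm, 4 dense, 5 dense, 6 tanh dense;
  # frozen = conv, lstm, first dense; trainable = last two dense layers
  frozenNames <- grep("^layer[1-4]\\.", names(donor), value = TRUE)
  for (nm in frozenNames)
    expect_identical(after[[nm]], donor[[nm]], label = nm)
  trainableNames <- grep("^layer[56]\\.", names(donor), value = TRUE)
  expect_true(any(vapply(trainableNames, function(nm)
    !identical(after[[nm]], donor[[nm]]), logical(1))))
})

test_that("fixed-dense control freezes the whole sequence trunk", {
  sp <- quickSplit()
  ctrl <- trainFixedDenseControl(quickSeqRun(), sp$train, sp$val,
                                 chrConfig = quickChrConfig(), seed = 402L,
                                 epochs = 1L, batchSize = 32L, posFrac = 0.5,
                                 lr = 3e-3)
  expect_equal(ctrl@mode, "fixed_dense_control")
  donor <- seqchrom:::nnParams(trainedModel(quickSeqRun())@trunk)
  after <- seqchrom:::nnParams(ctrl@config$finalModel@seqTrunk)
  expect_identical(after, donor)
})

test_that("one-SE selection only departs for a clear validation gain", {
  bimRun <- quickBimRun()
  expect_equal(bimRun@config$selection, "oneSE")
  h <- runHistory(bimRun)
  se <- bimRun@config$selectionSe
  expect_gte(se, 0)
  trained <- h$valAuprc[h$epoch > 0]
  if (bimRun@bestEpoch == 0L) {
    expect_true(all(!is.finite(trained) | trained <= h$valAuprc[1] + se))
  } else {
    expect_gt(h$valAuprc[h$epoch == bimRun@bestEpoch],
              h$valAuprc[1] + se)
  }
})

test_that("the bimodal warm start reproduces the donor at epoch zero", {
  sp <- quickSplit()
  seqRun <- quickSeqRun()
  bim <- transferAndTrainBimodal(seqRun, sp$train, sp$val,
                                 chrConfig = quickChrConfig(), seed = 403L,
                                 epochs = 1L, batchSize = 32L, posFrac = 0.5,
                                 lr = 3e-3)
  h <- runHistory(bim)
  expect_equal(h$epoch[1], 0L)
  yv <- as.numeric(bindingLabels(sp$val) == "bound")
  donorVal <- auprc(predictProb(trainedModel(seqRun), seqOneHot(sp$val)), yv)
  expect_equal(h$valAuprc[1], donorVal, tolerance = 1e-12)
})

test_that("training stays finite even at an absurd learning rate", {
  # bounded activations (tanh head, clipped cross-entropy) keep the loss
  # finite; the divergence guard in the training loop is defensive and not
  # reachable from valid inputs
  sp <- quickSplit()
  run <- trainSequenceNetwork(sp$train, sp$val, config = quickSeqConfig(),
                              sampler = "random", seed = 1L, epochs = 1L,
                              batchSize = 32L, posFrac = 0.5, lr = 1e6)
  expect_true(all(is.finite(runHistory(run)$trainLoss)))
})

test_that("TrainingRun accessors expose model and history", {
  run <- quickSeqRun()
  expect_s4_class(trainedModel(run), "SequenceModel")
  h <- runHistory(run)
  expect_true(all(c("epoch", "trainLoss", "valAuprc") %in% names(h)))
  expect_gte(run@bestEpoch, 1L)
})
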