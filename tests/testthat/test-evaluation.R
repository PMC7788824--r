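# Reference implementations by exhaustive threshold enumeration, used as
# oracles for the vectorized tied-block metrics.

refMetrics <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  prec <- tp / (tp + fp); rec <- tp / nPos
  auprc <- sum(diff(c(0, rec)) * prec)
  list(thr = thr, precision = prec, recall = rec, auprc = auprc,
       fpr = fp / nNeg, tp = tp)
}

test_that("prCurve and auprc agree with enumeration on random tied vectors", {
  set.seed(100)
  for (rep in 1:200) {
    n <- sample(2:30, 1)
    labels <- rbinom(n, 1, 0.4)
    if (!any(labels == 1)) labels[sample(n, 1)] <- 1
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    ref <- refMetrics(scores, labels)
    curve <- prCurve(scores, labels)
    expect_equal(curve$threshold, ref$thr)
    expect_equal(curve$precision, ref$precision)
    expect_equal(curve$recall, ref$recall)
    expect_equal(auprc(curve), ref$auprc, tolerance = 1e-12)
    expect_equal(attr(curve, "prevalence"), mean(labels))
  }
})

test_that("precisionAtRecall picks the first crossing of the sweep", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    labels <- rbinom(n, 1, 0.5)
    if (!any(labels == 1)) labels[1] <- 1
    scores <- sample(seq(0, 1, 0.2), n, replace = TRUE)
    ref <- refMetrics(scores, labels)
    curve <- prCurve(scores, labels)
    for (r in c(0.25, 0.5, 1)) {
      i <- which(ref$recall >= r)[1]
      expect_equal(precisionAtRecall(curve, r), ref$precision[i])
    }
  }
  expect_error(precisionAtRecall(prCurve(c(1, 0), c(1, 0)), 1.5),
               "not attained")
})

test_that("recallAtFpr maximizes recall under the FPR bound", {
  set.seed(102)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    ref <- refMetrics(scores, labels)
    for (f in c(0, 0.05, 0.2, 0.5)) {
      ok <- which(ref$fpr <= f)
      # no admissible threshold: predicting nothing gives recall 0
      want <- if (length(ok)) max(ref$tp[ok]) / sum(labels == 1) else 0
      got <- recallAtFpr(scores, labels, fpr = f)
      expect_equal(got$recall, want)
      expect_lte(sum(scores >= got$threshold & labels == 0) /
                   sum(labels == 0), f)
      expect_equal(got$tp + got$fn, sum(labels == 1))
    }
  }
  expect_error(recallAtFpr(c(1, 2), c(1, 1), 0.05), "both positives")
})

test_that("perfect and random scorers hit their analytic auPRC", {
  y <- rep(c(1, 0), c(20, 80))
  expect_equal(auprc(prCurve(seq(1, 0, length.out = 100), y)), 1)
  # random scorer approaches prevalence for large n
  set.seed(103)
  n <- 1e5
  y <- rbinom(n, 1, 0.1)
  s <- runif(n)
  expect_equal(auprc(prCurve(s, y)), mean(y), tolerance = 0.01)
})

test_that("recall posterior follows the Beta(TP+1, FN+1) closed form", {
  set.seed(104)
  for (rep in 1:50) {
    tp <- sample(0:200, 1); fn <- sample(0:200, 1)
    if (tp + fn == 0) tp <- 1
    rp <- recallPosterior(tp, fn)
    expect_equal(rp@alpha, tp + 1)
    expect_equal(rp@beta, fn + 1)
    if (tp + fn > 0)
      expect_equal(posteriorMode(rp), tp / (tp + fn), tolerance = 1e-12)
    expect_equal(posteriorMean(rp), (tp + 1) / (tp + fn + 2))
    ci <- credibleInterval(rp)
    expect_equal(ci, qbeta(c(0.025, 0.975), tp + 1, fn + 1))
  }
  expect_equal(posteriorMode(recallPosterior(0, 5)), 0)
  expect_equal(posteriorMode(recallPosterior(5, 0)), 1)
  expect_error(recallPosterior(0, 0), "at least 1")
})

test_that("credible interval narrows with N at fixed observed recall", {
  widths <- vapply(c(10, 40, 160, 640), function(N) {
    ci <- credibleInterval(recallPosterior(0.25 * N, 0.75 * N))
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("compareModels performs the exact paired signed-rank test", {
  a <- c(0.40, 0.42, 0.38, 0.45, 0.41, 0.39, 0.44, 0.43, 0.37)
  b <- a + seq(0.01, 0.09, by = 0.01)    # nine distinct positive differences
  res <- compareModels(a, b, alternative = "greater")
  expect_equal(res$pValue, 1 / 512)      # 1 / 2^9
  expect_equal(res$medianDelta, 0.05)
  expect_equal(res$n, 9L)
  # agreement with stats::wilcox.test on untied data
  set.seed(105)
  x <- runif(8); y <- x + rnorm(8, 0, 0.1)
  res2 <- compareModels(x, y)
  ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE)
  expect_equal(res2$pValue, ref$p.value)
  # degenerate and error cases
  expect_equal(compareModels(a, a)$pValue, 1)
  expect_error(compareModels(1, 2), "fewer than 2")
  expect_error(compareModels(1:3, 1:4), "not paired")
})

test_that("compareModels pairs data.frame folds by name", {
  dfA <- data.frame(fold = c("c1", "c2", "c3"), auprc = c(0.3, 0.4, 0.5))
  dfB <- data.frame(fold = c("c3", "c1", "c2"), auprc = c(0.7, 0.5, 0.6))
  res <- suppressWarnings(compareModels(dfA, dfB))  # tied deltas
  expect_equal(res$medianDelta, 0.2)
})
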