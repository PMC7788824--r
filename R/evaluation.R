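#' Precision-recall curve
#'
#' Sweeps all distinct score thresholds (tied scores share a threshold,
#' highest first) and records precision and recall for the classifier
#' "predict bound if score >= threshold".
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = bound); at least one positive required.
#' @return data.frame (threshold, tp, fp, precision, recall) with attribute
#'   \code{prevalence}.
#' @export
prCurve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  nPos <- sum(labels == 1)
  if (nPos == 0) stop("precision-recall undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cumTP <- cumsum(y == 1)
  cumFP <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tied block
  out <- data.frame(threshold = s[last],
                    tp = cumTP[last], fp = cumFP[last])
  out$precision <- out$tp / (out$tp + out$fp)
  out$recall <- out$tp / nPos
  attr(out, "prevalence") <- nPos / length(labels)
  out
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) integration:
#' sum over thresholds of (recall_t - recall_{t-1}) * precision_t.
#'
#' @param curve From \code{\link{prCurve}} (or scores if \code{labels} given).
#' @param labels Optional; if supplied, \code{curve} is taken to be scores.
#' @return auPRC in [0, 1].
#' @export
auprc <- function(curve, labels = NULL) {
  if (!is.null(labels)) curve <- prCurve(curve, labels)
  sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Precision at a fixed recall
#'
#' Precision at the first threshold (sweeping from the highest score down)
#' whose recall reaches \code{r} -- the operating point "precision at fixed
#' recall r".
#'
#' @param curve From \code{\link{prCurve}}.
#' @param r Target recall (default 0.5).
#' @return Precision at that operating point.
#' @export
precisionAtRecall <- function(curve, r = 0.5) {
  hit <- which(curve$recall >= r)
  if (!length(hit)) stop("recall ", r, " not attained by this classifier")
  curve$precision[hit[1]]
}

#' Recall at a fixed false positive rate
#'
#' The decision threshold is the smallest score such that the empirical FPR
#' does not exceed \code{fpr} (maximizing recall subject to the FPR bound);
#' recall, TP and FN are reported at that threshold.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels with at least one positive and one negative.
#' @param fpr FPR bound (default 0.05).
#' @return List (recall, tp, fn, threshold).
#' @export
recallAtFpr <- function(scores, labels, fpr = 0.05) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("recall at fixed FPR needs both positives and negatives")
  thr <- sort(unique(scores), decreasing = TRUE)
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  ok <- which(fp / nNeg <= fpr)
  t <- thr[ok[length(ok)]]   # smallest admissible threshold
  tp <- sum(scores >= t & labels == 1)
  list(recall = tp / nPos, tp = tp, fn = nPos - tp, threshold = t)
}

#' Posterior distribution of the true recall
#'
#' Models the observed recall as TP successes out of N = TP + FN draws from
#' Binomial(N, r) with a uniform Beta(a = 1, b = 1) prior on r, giving the
#' Beta(TP + a, FN + b) posterior. With the uniform prior the posterior mode
#' equals the observed recall TP/N, and the credible interval narrows as N
#' grows -- factors with few binding events get honest, wide posteriors.
#'
#' @param tp,fn Non-negative counts, tp + fn >= 1.
#' @param a,b Beta prior parameters (default 1, 1).
#' @return A \linkS4class{RecallPosterior}.
#' @examples
#' rp <- recallPosterior(5, 5)
#' posteriorMode(rp)        # 0.5
#' credibleInterval(rp)
#' @export
recallPosterior <- function(tp, fn, a = 1, b = 1) {
  stopifnot(tp >= 0, fn >= 0, a > 0, b > 0)
  if (tp + fn < 1) stop("N = TP + FN must be at least 1")
  methods::new("RecallPosterior", alpha = tp + a, beta = fn + b,
               tp = as.numeric(tp), fn = as.numeric(fn))
}

#' @rdname RecallPosterior-class
#' @export
setMethod("posteriorMode", "RecallPosterior", function(object) {
  a <- object@alpha; b <- object@beta
  if (a > 1 && b > 1) (a - 1) / (a + b - 2)
  else if (a <= 1 && b > 1) 0
  else if (a > 1 && b <= 1) 1
  else NA_real_
})

#' @rdname RecallPosterior-class
#' @export
setMethod("posteriorMean", "RecallPosterior", function(object)
  object@alpha / (object@alpha + object@beta))

#' @rdname RecallPosterior-class
#' @export
setMethod("credibleInterval", "RecallPosterior", function(object, level = 0.95) {
  half <- (1 - level) / 2
  stats::qbeta(c(half, 1 - half), object@alpha, object@beta)
})

setMethod("show", "RecallPosterior", function(object) {
  ci <- credibleInterval(object)
  cat(sprintf("RecallPosterior: Beta(%g, %g), mode %.3f, 95%% CI [%.3f, %.3f]\n",
              object@alpha, object@beta, posteriorMode(object), ci[1], ci[2]))
})

#' Paired fold-wise model comparison
#'
#' Wilcoxon signed-rank test on a metric paired by held-out chromosome, plus
#' the median per-fold difference (B minus A).
#'
#' @param metricsA,metricsB Either numeric vectors (paired by position) or
#'   data.frames with columns \code{fold} and the metric.
#' @param metric Metric column when data.frames are given (default "auprc").
#' @param alternative Passed to \code{\link[stats]{wilcox.test}}.
#' @return List (statistic, pValue, medianDelta, n).
#' @export
compareModels <- function(metricsA, metricsB, metric = "auprc",
                          alternative = "two.sided") {
  if (is.data.frame(metricsA)) {
    if (!all(metricsA$fold %in% metricsB$fold) ||
        nrow(metricsA) != nrow(metricsB))
      stop("fold metrics are not paired")
    metricsB <- metricsB[match(metricsA$fold, metricsB$fold), ]
    a <- metricsA[[metric]]; b <- metricsB[[metric]]
  } else {
    if (length(metricsA) != length(metricsB))
      stop("fold metrics are not paired")
    a <- metricsA; b <- metricsB
  }
  if (length(a) < 2) stop("paired test undefined for fewer than 2 folds")
  if (all(b == a)) {
    return(list(statistic = NA_real_, pValue = 1,
                medianDelta = 0, n = length(a)))
  }
  wt <- stats::wilcox.test(b, a, paired = TRUE, alternative = alternative,
                           exact = TRUE)
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       medianDelta = stats::median(b - a), n = length(a))
}

#' Evaluate a model on a labeled dataset
#'
#' Scores every non-ambiguous window and reports auPRC, recall at fixed FPR
#' (with the recall posterior), and precision at fixed recall.
#'
#' @param model A \linkS4class{SequenceModel} or \linkS4class{BimodalModel}.
#' @param dataset A labeled \linkS4class{ChromDataset}.
#' @param fpr FPR for the recall operating point (default 0.05).
#' @param recallTarget Recall for the precision operating point (default 0.5).
#' @return List (auprc, recallAtFpr, posterior, precisionAtRecall, n, nPos).
#' @export
evaluateModel <- function(model, dataset, fpr = 0.05, recallTarget = 0.5) {
  keep <- is.na(bindingLabels(dataset)) |
    bindingLabels(dataset) != "ambiguous"
  ds <- dataset[keep]
  y <- as.numeric(bindingLabels(ds) == "bound")
  sc <- if (methods::is(model, "SequenceModel"))
    predictProb(model, seqOneHot(ds)) else predictProb(model, ds)
  curve <- prCurve(sc, y)
  raf <- recallAtFpr(sc, y, fpr = fpr)
  list(auprc = auprc(curve),
       recallAtFpr = raf$recall,
       posterior = recallPosterior(raf$tp, raf$fn),
       precisionAtRecall = tryCatch(precisionAtRecall(curve, recallTarget),
                                    error = function(e) NA_real_),
       n = length(y), nPos = sum(y))
}
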