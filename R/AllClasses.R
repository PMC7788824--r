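#' @import methods
#' @importFrom S4Vectors DataFrame Rle runValue runLength
#' @importClassesFrom S4Vectors Rle
#' @importClassesFrom IRanges RleList
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Point binding events with significance
#'
#' A set of transcription-factor binding events called by a point-event peak
#' caller, each a single genomic coordinate with an associated p-value.
#' Events at or below the significance threshold (default 0.001) define
#' bound windows downstream; the remaining events mark windows as ambiguous.
#'
#' @slot events A width-1 \link[GenomicRanges]{GRanges} with a numeric
#'   \code{pvalue} metadata column in [0, 1].
#' @slot pThreshold Significance cutoff; events with p <= pThreshold are
#'   significant.
#' @exportClass PeakSet
setClass("PeakSet",
  slots = c(events = "GRanges", pThreshold = "numeric"))

setValidity("PeakSet", function(object) {
  msg <- character(0)
  pv <- object@events$pvalue
  if (is.null(pv)) msg <- c(msg, "events must carry a 'pvalue' metadata column")
  else if (any(!is.finite(pv)) || any(pv < 0 | pv > 1))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(object@events) && any(GenomicRanges::width(object@events) != 1L))
    msg <- c(msg, "events must be width-1 points")
  if (length(object@pThreshold) != 1L || object@pThreshold <= 0 ||
      object@pThreshold > 1)
    msg <- c(msg, "pThreshold must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-base read coverage for one replicate of one chromatin track
#'
#' @slot cov An \link[IRanges]{RleList} of per-base read counts, one Rle per
#'   chromosome.
#' @slot replicate Replicate identifier.
#' @slot totalTags Total tag count (sum of per-base counts), used for
#'   library-size normalization.
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  slots = c(cov = "RleList", replicate = "character", totalTags = "numeric"))

setValidity("CoverageTrack", function(object) {
  msg <- character(0)
  tot <- sum(vapply(object@cov, function(r) sum(as.numeric(runValue(r)) *
                                                 runLength(r)), numeric(1)))
  if (any(vapply(object@cov, function(r) any(runValue(r) < 0 |
                                             !is.finite(runValue(r))), logical(1))))
    msg <- c(msg, "coverage values must be finite and >= 0")
  if (abs(tot - object@totalTags) > 1e-6 * max(1, tot))
    msg <- c(msg, "totalTags must equal the sum of per-base counts")
  if (length(msg)) msg else TRUE
})

#' Tensorized, labeled genomic windows
#'
#' The central training container: N fixed-width genomic windows with, per
#' window, the DNA sequence (stored compactly as integer codes, expanded to a
#' one-hot width x 4 matrix on access), a binned chromatin feature tensor
#' (nBins x k tracks, library-size normalized and replicate-averaged), a
#' binding label, and a prior-accessibility flag.
#'
#' Sequence codes are 1=A, 2=C, 3=G, 4=T, 0=N; one-hot rows for N are
#' all-zero, so observed data never coincides with the uniform 0.25 baseline
#' used by integrated gradients.
#'
#' @slot rowRanges Window coordinates (\link[GenomicRanges]{GRanges}).
#' @slot seqCode Integer matrix, N x width.
#' @slot chromFeat Numeric array, N x nBins x k.
#' @slot label Factor with levels unbound, bound, ambiguous (NA = unlabeled).
#' @slot accessible Logical (NA until \code{\link{assignAccessibility}}).
#' @slot trackNames Names of the k chromatin tracks.
#' @slot normTotal Library size each replicate was scaled to.
#' @exportClass ChromDataset
setClass("ChromDataset",
  slots = c(rowRanges = "GRanges", seqCode = "matrix", chromFeat = "array",
            label = "factor", accessible = "logical",
            trackNames = "character", normTotal = "numeric"))

setValidity("ChromDataset", function(object) {
  msg <- character(0)
  n <- length(object@rowRanges)
  if (nrow(object@seqCode) != n) msg <- c(msg, "seqCode rows != windows")
  if (dim(object@chromFeat)[1] != n) msg <- c(msg, "chromFeat rows != windows")
  if (length(dim(object@chromFeat)) != 3L)
    msg <- c(msg, "chromFeat must be N x nBins x k")
  else if (dim(object@chromFeat)[3] != length(object@trackNames))
    msg <- c(msg, "chromFeat track dimension != length(trackNames)")
  if (length(object@label) != n) msg <- c(msg, "label length != windows")
  if (length(object@accessible) != n) msg <- c(msg, "accessible length != windows")
  if (!all(levels(object@label) == c("unbound", "bound", "ambiguous")))
    msg <- c(msg, "label levels must be unbound, bound, ambiguous")
  if (any(object@chromFeat < 0) || any(!is.finite(object@chromFeat)))
    msg <- c(msg, "chromatin features must be finite and >= 0")
  if (n && length(unique(GenomicRanges::width(object@rowRanges))) != 1L)
    msg <- c(msg, "all windows must share one width")
  if (length(msg)) msg else TRUE
})

#' Sequence-only binding model
#'
#' The sequence trunk (conv - maxpool - LSTM - dense stack ending in a single
#' tanh node, output phi in (-1,1)) followed by a scalar sigmoid head:
#' P(bound) = sigmoid(w * phi + b). The trunk is architecturally identical to
#' the bimodal model's sequence sub-network, so its weights transfer without
#' reshaping.
#'
#' @slot trunk Layer stack (internal representation).
#' @slot head Numeric c(w, b).
#' @slot config Architecture configuration list.
#' @exportClass SequenceModel
setClass("SequenceModel",
  slots = c(trunk = "list", head = "numeric", config = "list"))

#' Additive bimodal binding model
#'
#' Two bounded sub-networks and a linear combiner on the logit scale:
#' logit(y) = beta0 + betaS * phiS(X_S) + betaC * phiC(X_C), with
#' phiS, phiC in (-1, 1) (tanh heads). The combiner has exactly three scalar
#' parameters so the two-dimensional latent decomposition
#' (seqscore = betaS * phiS, chromscore = betaC * phiC) is exact by
#' construction, not an approximation.
#'
#' @slot seqTrunk Sequence sub-network layer stack.
#' @slot chrTrunk Chromatin sub-network layer stack.
#' @slot beta Numeric c(b0, bS, bC).
#' @slot kTracks Number of chromatin tracks the model expects.
#' @slot config Architecture configuration list.
#' @exportClass BimodalModel
setClass("BimodalModel",
  slots = c(seqTrunk = "list", chrTrunk = "list", beta = "numeric",
            kTracks = "integer", config = "list"))

#' One completed training run
#'
#' @slot mode One of sequence_only, bimodal, or fixed_dense_control.
#' @slot seed Integer seed the run was launched with.
#' @slot history Per-epoch data.frame (epoch, trainLoss, valAuprc).
#' @slot model The best-validation-epoch model.
#' @slot bestEpoch Epoch whose validation auPRC selected the model.
#' @slot config Training configuration (sampler, batch size, ...).
#' @exportClass TrainingRun
setClass("TrainingRun",
  slots = c(mode = "character", seed = "integer", history = "data.frame",
            model = "ANY", bestEpoch = "integer", config = "list"))

#' Two-dimensional latent decomposition of predictions
#'
#' Per window, seqscore = betaS * phiS and chromscore = betaC * phiC; by the
#' additive architecture logit(prob) - beta0 = seqscore + chromscore exactly
#' (the largest observed residual is recorded and checked at construction).
#'
#' @slot rowRanges Window coordinates.
#' @slot seqscore,chromscore,prob Numeric, one value per window.
#' @slot label,accessible Copied from the scored dataset.
#' @slot beta Combiner weights c(b0, bS, bC) of the scoring model.
#' @slot maxResidual Largest additivity residual over all windows.
#' @exportClass LatentEmbedding
setClass("LatentEmbedding",
  slots = c(rowRanges = "GRanges", seqscore = "numeric", chromscore = "numeric",
            prob = "numeric", label = "factor", accessible = "logical",
            beta = "numeric", maxResidual = "numeric"))

setValidity("LatentEmbedding", function(object) {
  n <- length(object@rowRanges)
  if (length(object@seqscore) != n || length(object@chromscore) != n ||
      length(object@prob) != n)
    return("score vectors must have one entry per window")
  if (object@maxResidual > 1e-5)
    return("additive decomposition violated: max residual > 1e-5")
  TRUE
})

#' Beta posterior over the true recall
#'
#' With TP true positives and FN false negatives on a held-out chromosome and
#' a uniform Beta(1, 1) prior on the true recall r of Recall ~ Binomial(N, r),
#' the posterior is Beta(TP + 1, FN + 1). Its mode is the observed recall
#' TP / N, and its credible intervals widen as N shrinks, quantifying the
#' uncertainty of recall estimates for factors with few binding events.
#'
#' @slot alpha,beta Posterior shape parameters.
#' @slot tp,fn Observed counts.
#' @exportClass RecallPosterior
setClass("RecallPosterior",
  slots = c(alpha = "numeric", beta = "numeric", tp = "numeric", fn = "numeric"))

setValidity("RecallPosterior", function(object) {
  if (object@alpha <= 0 || object@beta <= 0)
    return("posterior shape parameters must be positive")
  if (object@tp < 0 || object@fn < 0) return("counts must be >= 0")
  TRUE
})
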