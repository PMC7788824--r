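#' @rdname ChromDataset-class
#' @param x,object A ChromDataset.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname ChromDataset-class
#' @export
setGeneric("kTracks", function(x) standardGeneric("kTracks"))

#' @rdname ChromDataset-class
#' @export
setGeneric("windowRanges", function(x) standardGeneric("windowRanges"))

#' @rdname ChromDataset-class
#' @export
setGeneric("bindingLabels", function(x) standardGeneric("bindingLabels"))

#' @rdname ChromDataset-class
#' @param value Replacement value.
#' @export
setGeneric("bindingLabels<-", function(x, value) standardGeneric("bindingLabels<-"))

#' @rdname ChromDataset-class
#' @export
setGeneric("accessibility", function(x) standardGeneric("accessibility"))

#' @rdname ChromDataset-class
#' @export
setGeneric("accessibility<-", function(x, value) standardGeneric("accessibility<-"))

#' @rdname ChromDataset-class
#' @param idx Integer window indices (default: all windows).
#' @export
setGeneric("seqOneHot", function(x, idx) standardGeneric("seqOneHot"))

#' @rdname ChromDataset-class
#' @export
setGeneric("chromSignal", function(x, idx) standardGeneric("chromSignal"))

#' Score windows with a trained model
#'
#' \code{predictProb} returns the predicted binding probability;
#' \code{seqActivations} and \code{chromActivations} return the bounded
#' sub-network outputs phiS and phiC in (-1, 1).
#'
#' @param model A \linkS4class{SequenceModel} or \linkS4class{BimodalModel}.
#' @param newdata A \linkS4class{ChromDataset}, or for sequence scoring a
#'   (batch, width, 4) one-hot array.
#' @param ... Passed to methods.
#' @return Numeric vector, one value per window.
#' @export
setGeneric("predictProb", function(model, newdata, ...) standardGeneric("predictProb"))

#' @rdname predictProb
#' @export
setGeneric("seqActivations", function(model, newdata, ...) standardGeneric("seqActivations"))

#' @rdname predictProb
#' @export
setGeneric("chromActivations", function(model, newdata, ...) standardGeneric("chromActivations"))

#' @rdname RecallPosterior-class
#' @param object A RecallPosterior.
#' @export
setGeneric("posteriorMode", function(object) standardGeneric("posteriorMode"))

#' @rdname RecallPosterior-class
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))

#' @rdname RecallPosterior-class
#' @param level Credible level (default 0.95).
#' @export
setGeneric("credibleInterval", function(object, level = 0.95) standardGeneric("credibleInterval"))

#' @rdname TrainingRun-class
#' @param x A TrainingRun.
#' @export
setGeneric("trainedModel", function(x) standardGeneric("trainedModel"))

#' @rdname TrainingRun-class
#' @export
setGeneric("runHistory", function(x) standardGeneric("runHistory"))
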