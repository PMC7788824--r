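#' Latent two-dimensional embedding of windows
#'
#' Scores every window with the bimodal model and decomposes the prediction
#' exactly: seqscore = betaS * phiS, chromscore = betaC * phiC, so
#' logit(prob) = beta0 + seqscore + chromscore. The maximum additivity
#' residual over the dataset is recorded and must stay below 1e-5.
#'
#' @param model A trained \linkS4class{BimodalModel}.
#' @param dataset A \linkS4class{ChromDataset} tensorized with the same k and
#'   channel order.
#' @return A \linkS4class{LatentEmbedding}.
#' @export
latentEmbed <- function(model, dataset) {
  stopifnot(methods::is(model, "BimodalModel"))
  phiS <- seqActivations(model, dataset)
  phiC <- chromActivations(model, dataset)
  b <- model@beta
  seqscore <- b[["bS"]] * phiS
  chromscore <- b[["bC"]] * phiC
  logit <- b[["b0"]] + seqscore + chromscore
  prob <- stableSigmoid(logit)
  resid <- max(abs(stats::qlogis(prob) - logit), 0)
  methods::new("LatentEmbedding",
               rowRanges = windowRanges(dataset),
               seqscore = seqscore, chromscore = chromscore, prob = prob,
               label = bindingLabels(dataset),
               accessible = accessibility(dataset),
               beta = b, maxResidual = resid)
}

#' @rdname latentEmbed
#' @param x A LatentEmbedding.
#' @param ... Unused.
#' @export
as.data.frame.LatentEmbedding <- function(x, ...) {
  gr <- x@rowRanges
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             label = as.character(x@label),
             accessible = x@accessible,
             seqscore = x@seqscore, chromscore = x@chromscore,
             prob = x@prob)
}

setMethod("show", "LatentEmbedding", function(object) {
  cat("LatentEmbedding:", length(object@rowRanges), "windows;",
      "max additivity residual", format(object@maxResidual, digits = 3), "\n")
})

# nearest-rank top/bottom q sets over bound windows, ties by genomic order
boundQuartileSets <- function(emb, q) {
  bound <- which(!is.na(emb@label) & emb@label == "bound")
  k <- floor(q * length(bound))
  list(bound = bound,
       topSeq = bound[topKByOrder(emb@seqscore[bound], k, TRUE)],
       botSeq = bound[topKByOrder(emb@seqscore[bound], k, FALSE)],
       topChr = bound[topKByOrder(emb@chromscore[bound], k, TRUE)],
       botChr = bound[topKByOrder(emb@chromscore[bound], k, FALSE)])
}

#' Sequence-predicted and chromatin-predicted site sets
#'
#' Among bound windows only, SP sites fall in the top \code{q} fraction of
#' seqscores and the bottom \code{q} fraction of chromscores; CP sites are
#' the converse. Cut-points use the nearest-rank rule with ties broken by
#' genomic order, so each set holds at most floor(q * nBound) windows and
#' the two sets are disjoint by construction (for q <= 0.5).
#'
#' @param embedding A \linkS4class{LatentEmbedding}.
#' @param q Percentile fraction (default 0.25).
#' @return List with integer window ids \code{sp} and \code{cp} plus GRanges
#'   \code{spRanges}, \code{cpRanges}.
#' @export
extractSpCp <- function(embedding, q = 0.25) {
  sets <- boundQuartileSets(embedding, q)
  if (length(sets$bound) < 8) stop("need at least 8 bound windows")
  sp <- intersect(sets$topSeq, sets$botChr)
  cp <- intersect(sets$topChr, sets$botSeq)
  if (q <= 0.5 && length(intersect(sp, cp)))
    stop("internal error: SP and CP overlap")
  list(sp = sp, cp = cp,
       spRanges = embedding@rowRanges[sp],
       cpRanges = embedding@rowRanges[cp])
}

#' Mean chromatin signal per score stratum
#'
#' Divides bound windows into \code{nStrata} nearest-rank strata of the
#' chosen latent score and reports, per stratum and chromatin track, the
#' mean window-level signal (the 10 bins averaged per window).
#'
#' @param embedding A \linkS4class{LatentEmbedding}.
#' @param dataset The dataset the embedding was computed from.
#' @param score "seqscore" or "chromscore".
#' @param nStrata Number of strata (default 4, quartiles).
#' @return data.frame (stratum, track, mean); stratum 1 is the lowest score.
#' @export
stratumSummaries <- function(embedding, dataset, score = c("seqscore",
                                                           "chromscore"),
                             nStrata = 4L) {
  score <- match.arg(score)
  bound <- which(!is.na(embedding@label) & embedding@label == "bound")
  if (length(bound) < nStrata) stop("fewer bound windows than strata")
  v <- methods::slot(embedding, score)[bound]
  ord <- order(v, bound)                 # ties by genomic order
  stratum <- integer(length(bound))
  stratum[ord] <- ceiling(seq_along(ord) / (length(ord) / nStrata))
  stratum[stratum > nStrata] <- nStrata
  sig <- chromSignal(dataset, bound)
  winMean <- apply(sig, c(1, 3), mean)   # bound x k
  out <- expand.grid(stratum = seq_len(nStrata),
                     track = dataset@trackNames, stringsAsFactors = FALSE)
  out$mean <- mapply(function(s, tr) {
    j <- match(tr, dataset@trackNames)
    mean(winMean[stratum == s, j])
  }, out$stratum, out$track)
  out
}

#' Score distributions across labeled interval classes
#'
#' Assigns each window to the class of the interval containing its midpoint
#' (first interval in file order on overlap, with multiplicities counted)
#' and summarizes the chosen latent score per class.
#'
#' @param embedding A \linkS4class{LatentEmbedding}.
#' @param intervals \link[GenomicRanges]{GRanges} with a \code{class}
#'   metadata column (e.g. chromatin domains or state segmentations).
#' @param score "seqscore" or "chromscore".
#' @return data.frame (class, n, median, q25, q75, nMultiAssigned).
#' @export
intervalScoreSummary <- function(embedding, intervals,
                                 score = c("chromscore", "seqscore")) {
  score <- match.arg(score)
  if (is.null(intervals$class)) stop("intervals need a 'class' column")
  gr <- embedding@rowRanges
  mids <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(start = (GenomicRanges::start(gr) +
                                GenomicRanges::end(gr)) %/% 2L, width = 1L))
  hits <- GenomicRanges::findOverlaps(mids, intervals)
  first <- !duplicated(S4Vectors::queryHits(hits))
  multi <- sum(!first)
  cls <- rep(NA_character_, length(gr))
  cls[S4Vectors::queryHits(hits)[first]] <-
    as.character(intervals$class[S4Vectors::subjectHits(hits)[first]])
  v <- methods::slot(embedding, score)
  out <- do.call(rbind, lapply(unique(as.character(intervals$class)),
    function(cl) {
      vv <- v[!is.na(cls) & cls == cl]
      if (!length(vv))
        data.frame(class = cl, n = 0L, median = NA_real_, q25 = NA_real_,
                   q75 = NA_real_)
      else
        data.frame(class = cl, n = length(vv), median = stats::median(vv),
                   q25 = nearestRankQuantile(vv, 0.25),
                   q75 = nearestRankQuantile(vv, 0.75))
    }))
  attr(out, "nMultiAssigned") <- multi
  out
}

#' Fraction of one site set overlapping another
#'
#' @param siteSetA,siteSetB \link[GenomicRanges]{GRanges} of sites (windows
#'   or points).
#' @param slop Extra bp of tolerance on each side (maxgap).
#' @return Fraction of A sites within \code{slop} of any B site.
#' @export
overlapFraction <- function(siteSetA, siteSetB, slop = 0L) {
  if (length(siteSetA) == 0) stop("site set A is empty")
  mean(IRanges::overlapsAny(siteSetA, siteSetB, maxgap = slop))
}

#' Write an embedding as TSV
#' @param embedding A \linkS4class{LatentEmbedding}.
#' @param path Output file.
#' @export
writeEmbedding <- function(embedding, path) {
  utils::write.table(as.data.frame(embedding), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
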