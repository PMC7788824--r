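#' Per-position integrated-gradients attribution for one window
#'
#' @slot perPosition Attribution summed over the 4 channels, length L.
#' @slot perChannel L x 4 attribution matrix.
#' @slot x,baseline The input and reference one-hot (or fractional) matrices.
#' @slot m Number of path integration steps.
#' @slot fx,fBaseline Head values at x and at the baseline.
#' @exportClass AttributionTrack
setClass("AttributionTrack",
  slots = c(perPosition = "numeric", perChannel = "matrix", x = "matrix",
            baseline = "matrix", m = "integer", fx = "numeric",
            fBaseline = "numeric"))

setMethod("show", "AttributionTrack", function(object) {
  cat("AttributionTrack:", length(object@perPosition), "bp, m =", object@m,
      "; completeness residual",
      format(completenessResidual(object), digits = 3), "\n")
})

#' @rdname integratedGradients
#' @param track An AttributionTrack.
#' @export
completenessResidual <- function(track) {
  abs(sum(track@perChannel) - (track@fx - track@fBaseline))
}

# scalar differentiable head over the sequence trunk:
# sequence-only model -> logit = w * phi + b (gradient scale w);
# bimodal model       -> seqscore = bS * phiS (gradient scale bS)
seqHeadOf <- function(model) {
  if (methods::is(model, "SequenceModel"))
    list(trunk = model@trunk, scale = model@head[["w"]],
         offset = model@head[["b"]])
  else if (methods::is(model, "BimodalModel"))
    list(trunk = model@seqTrunk, scale = model@beta[["bS"]], offset = 0)
  else stop("model must be a SequenceModel or BimodalModel")
}

uniformBaseline <- function(L) matrix(0.25, L, 4)

# collapse a (B, 1, 1) conv output to the (B, 1) matrix the scalar heads
# expect, so single-full-width-filter (linear) trunks are legal models
scalarOut <- function(out) {
  d <- dim(out)
  if (length(d) == 3L && d[2] == 1L && d[3] == 1L) dim(out) <- d[1:2]
  out
}

#' Integrated gradients over a sequence window
#'
#' Attribution of the scalar sequence head (the sequence-only logit, or the
#' bimodal model's seqscore) to each input position, relative to the
#' uniform-composition reference in which every position is
#' [0.25, 0.25, 0.25, 0.25]. Gradients are averaged along the straight-line
#' path from baseline to input by an adaptive composite Simpson rule: the
#' path starts from m uniform subintervals (m rounded up to even) and any
#' panel whose half-panel Richardson estimate exceeds its share of the
#' tolerance is bisected, up to \code{maxDepth} levels. Max-pooling makes
#' the path derivative only piecewise smooth; the adaptive splits localize
#' those kinks, so the completeness axiom (attributions summing to
#' F(x) - F(baseline)) holds to roughly \code{tol} in relative terms
#' instead of stalling at the fixed-grid error floor. For a linear head the
#' integrand is constant and the result is exact with no refinement.
#'
#' @param model A \linkS4class{SequenceModel} or \linkS4class{BimodalModel}.
#' @param x One-hot (or fractional) L x 4 matrix for a single window.
#' @param baseline Reference matrix (default: uniform 0.25 composition).
#' @param m Base integration steps (default 128, minimum 2).
#' @param tol Target completeness residual relative to
#'   |F(x) - F(baseline)| (default 1e-3).
#' @param maxDepth Maximum panel bisection depth (default 12).
#' @return An \linkS4class{AttributionTrack}.
#' @export
integratedGradients <- function(model, x, baseline = NULL, m = 128L,
                                tol = 1e-3, maxDepth = 12L) {
  if (m < 2) stop("integrated gradients needs m >= 2 steps")
  head <- seqHeadOf(model)
  L <- nrow(x)
  if (ncol(x) != 4) stop("x must be an L x 4 matrix")
  if (is.null(baseline)) baseline <- uniformBaseline(L)
  stopifnot(identical(dim(baseline), dim(x)))
  diffs <- x - baseline
  m <- as.integer(m)
  if (m %% 2L) m <- m + 1L           # Simpson needs an even subdivision

  headVal <- function(z) {
    phi <- scalarOut(nnForward(head$trunk, array(z, c(1, L, 4)),
                               train = FALSE)$out)[1, 1]
    head$scale * phi + head$offset
  }
  fx <- headVal(x)
  fBaseline <- headVal(baseline)

  # batched gradient rows at path positions alphas: returns n x (4L) matrix
  gradRows <- function(alphas) {
    n <- length(alphas)
    path <- array(rep(as.vector(baseline), each = n), c(n, L, 4)) +
      array(outer(alphas, as.vector(diffs)), c(n, L, 4))
    fw <- nnForward(head$trunk, path, train = FALSE)
    bw <- nnBackward(head$trunk, fw$caches, matrix(head$scale, n, 1))
    dX <- bw$dX
    dim(dX) <- c(n, L * 4L)
    dX
  }

  alphas <- (0:m) / m
  G <- gradRows(alphas)                       # node table, one row per alpha
  g <- as.numeric(G %*% as.vector(diffs))     # scalar path derivative
  # panels as node-index triples (left, mid, right) into the node table
  panels <- cbind(a = seq(1L, m - 1L, by = 2L), c = seq(2L, m, by = 2L),
                  b = seq(3L, m + 1L, by = 2L))
  depth <- rep(0L, nrow(panels))
  tolAbs <- max(tol * abs(fx - fBaseline), 1e-10)

  intVec <- numeric(L * 4L)                   # accumulated vector integral
  while (nrow(panels)) {
    ia <- panels[, 1]; ic <- panels[, 2]; ib <- panels[, 3]
    h <- alphas[ib] - alphas[ia]
    # two new midpoint nodes per panel, evaluated in one batch
    ad <- (alphas[ia] + alphas[ic]) / 2
    ae <- (alphas[ic] + alphas[ib]) / 2
    newAlphas <- c(ad, ae)
    Gn <- gradRows(newAlphas)
    gn <- as.numeric(Gn %*% as.vector(diffs))
    id <- length(alphas) + seq_along(ad)
    ie <- length(alphas) + length(ad) + seq_along(ae)
    alphas <- c(alphas, newAlphas)
    G <- rbind(G, Gn)
    g <- c(g, gn)
    s1 <- h / 6 * (g[ia] + 4 * g[ic] + g[ib])
    s2 <- h / 12 * (g[ia] + 4 * g[id] + 2 * g[ic] + 4 * g[ie] + g[ib])
    accept <- abs(s2 - s1) <= 15 * tolAbs * h | depth >= maxDepth
    for (k in which(accept)) {
      wts <- c(1, 4, 2, 4, 1) * h[k] / 12
      s2v <- wts[1] * G[ia[k], ] + wts[2] * G[id[k], ] + wts[3] * G[ic[k], ] +
        wts[4] * G[ie[k], ] + wts[5] * G[ib[k], ]
      s1v <- h[k] / 6 * (G[ia[k], ] + 4 * G[ic[k], ] + G[ib[k], ])
      intVec <- intVec + s2v + (s2v - s1v) / 15    # Richardson correction
    }
    keep <- which(!accept)
    panels <- rbind(cbind(ia[keep], id[keep], ic[keep]),
                    cbind(ic[keep], ie[keep], ib[keep]))
    depth <- rep(depth[keep] + 1L, 2L)
  }

  meanGrad <- matrix(intVec, L, 4)
  perChannel <- diffs * meanGrad
  methods::new("AttributionTrack",
               perPosition = rowSums(perChannel), perChannel = perChannel,
               x = x, baseline = baseline, m = as.integer(m),
               fx = fx, fBaseline = fBaseline)
}

#' Attribution tracks for many dataset windows
#'
#' @param model Model with a sequence head.
#' @param dataset A \linkS4class{ChromDataset}.
#' @param idx Window indices to attribute (default: bound windows).
#' @param m Integration steps.
#' @return List of \linkS4class{AttributionTrack}s, named by window index.
#' @export
attributeWindows <- function(model, dataset, idx = NULL, m = 128L) {
  if (is.null(idx))
    idx <- which(!is.na(bindingLabels(dataset)) &
                   bindingLabels(dataset) == "bound")
  out <- lapply(idx, function(i)
    integratedGradients(model, seqOneHot(dataset, i)[1, , ], m = m))
  names(out) <- as.character(idx)
  out
}

#' Extract saliency hills from an attribution track
#'
#' Local maxima of the smoothed positive attribution signal that rise
#' strictly above the within-window quantile \code{minProminenceQ} are peak
#' candidates; each yields a hill of \code{2 * flank} bp centered on the
#' peak (truncated and flagged at window edges), and peaks closer than a
#' hill width are merged keeping the taller one.
#'
#' @param track An \linkS4class{AttributionTrack} (or numeric attribution
#'   vector).
#' @param seq Optional window sequence (character or DNAString) to extract
#'   hill subsequences from.
#' @param flank Half-width of a hill in bp (default 10, giving 20 bp hills).
#' @param minProminenceQ Quantile of the smoothed signal a peak must exceed
#'   (default 0.9).
#' @param smooth Moving-average width in bp (default 5).
#' @return data.frame (peak, start, end, height, truncated[, seq]), 0-based
#'   half-open coordinates within the window; empty if no hills.
#' @export
findHills <- function(track, seq = NULL, flank = 10L, minProminenceQ = 0.9,
                      smooth = 5L) {
  a <- if (methods::is(track, "AttributionTrack")) track@perPosition else track
  L <- length(a)
  sig <- pmax(a, 0)
  sm <- as.numeric(stats::filter(sig, rep(1 / smooth, smooth), sides = 2))
  sm[is.na(sm)] <- 0
  thr <- nearestRankQuantile(sm, minProminenceQ)
  isPeak <- c(FALSE, diff(sm) > 0) & c(diff(sm) <= 0, FALSE) & sm > thr
  peaks <- which(isPeak)
  empty <- data.frame(peak = integer(0), start = integer(0), end = integer(0),
                      height = numeric(0), truncated = logical(0))
  if (!is.null(seq)) empty$seq <- character(0)
  if (!length(peaks)) return(empty)
  peaks <- peaks[order(-sm[peaks], peaks)]
  kept <- integer(0)
  for (p in peaks)
    if (!length(kept) || all(abs(kept - p) >= 2L * flank))
      kept <- c(kept, p)
  kept <- sort(kept)
  start <- pmax(kept - 1L - flank, 0L)          # 0-based
  end <- pmin(kept - 1L + flank, L)
  out <- data.frame(peak = kept - 1L, start = start, end = end,
                    height = sm[kept],
                    truncated = (end - start) < 2L * flank)
  if (!is.null(seq)) {
    s <- as.character(seq)
    out$seq <- substring(s, out$start + 1L, out$end)
  }
  out
}

canonicalKmers <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' Cluster saliency hills by k-mer content
#'
#' Featurizes hills as binary presence vectors over strand-collapsed k-mers
#' (a k-mer and its reverse complement share a feature), keeps only k-mers
#' present in at least \code{minFrac} of hills, and runs Euclidean K-means.
#' Per cluster, the most enriched k-mers (in-cluster frequency over overall
#' frequency) are reported as a motif-level readout.
#'
#' @param hillSeqs Character vector or \link[Biostrings]{DNAStringSet} of
#'   hill sequences.
#' @param kmerLen k-mer length (default 5).
#' @param minFrac Minimum fraction of hills containing a k-mer (default 0.05).
#' @param K Number of clusters (default 5).
#' @param seed Seed for K-means restarts.
#' @param nstart K-means restarts (default 10).
#' @return List (cluster, sizes, topKmers, inertia, features).
#' @export
clusterHills <- function(hillSeqs, kmerLen = 5L, minFrac = 0.05, K = 5L,
                         seed = 1L, nstart = 10L) {
  seqs <- Biostrings::DNAStringSet(hillSeqs)
  if (length(seqs) < K) stop("need at least K hills")
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = kmerLen)
  canon <- canonicalKmers(colnames(counts))
  groups <- split(seq_len(ncol(counts)), canon)
  M <- vapply(groups, function(j) rowSums(counts[, j, drop = FALSE]),
              numeric(nrow(counts)))
  pres <- (M > 0) * 1
  keep <- colMeans(pres) >= minFrac
  if (!any(keep)) stop("no k-mer present in at least ", minFrac, " of hills")
  feat <- pres[, keep, drop = FALSE]
  uniq <- unique(feat)
  Keff <- min(K, nrow(uniq))
  withSeed(seed, {
    if (Keff == 1L) {
      km <- list(cluster = rep(1L, nrow(feat)), tot.withinss = 0)
    } else {
      km <- stats::kmeans(feat, centers = Keff, nstart = nstart)
    }
  })
  overall <- colMeans(feat)
  topKmers <- lapply(seq_len(Keff), function(cl) {
    inCl <- colMeans(feat[km$cluster == cl, , drop = FALSE])
    enr <- (inCl + 1e-9) / (overall + 1e-9)
    head(sort(stats::setNames(enr, colnames(feat)), decreasing = TRUE), 5)
  })
  list(cluster = km$cluster, sizes = tabulate(km$cluster, Keff),
       topKmers = topKmers, inertia = km$tot.withinss, features = feat)
}

#' Count IUPAC k-mer matches on both strands
#'
#' Counts, per sequence, the start positions (on the + strand) at which
#' either the k-mer or its reverse complement matches, so palindromic or
#' reverse-palindromic instances are not double-counted. IUPAC ambiguity
#' codes in the k-mer are honored; ambiguity in the subject is not.
#'
#' @param seqs Character vector or \link[Biostrings]{DNAStringSet}.
#' @param kmer IUPAC k-mer (default "CAGSTG", the E-box family with S = C/G).
#' @return Integer vector of per-sequence counts.
#' @examples
#' countIupacKmer("CAGCTGCAGGTG")  # 2
#' @export
countIupacKmer <- function(seqs, kmer = "CAGSTG") {
  if (!all(strsplit(toupper(kmer), "")[[1]] %in% names(iupacTable)))
    stop("invalid IUPAC code in k-mer: ", kmer)
  seqs <- Biostrings::DNAStringSet(seqs)
  pat <- Biostrings::DNAString(toupper(kmer))
  fwd <- Biostrings::vmatchPattern(pat, seqs, fixed = "subject")
  rev <- Biostrings::vmatchPattern(Biostrings::reverseComplement(pat), seqs,
                                   fixed = "subject")
  vapply(seq_along(seqs), function(i)
    length(union(BiocGenerics::start(fwd[[i]]), BiocGenerics::start(rev[[i]]))),
    integer(1))
}

# score integer code matrices through the sequence head in memory chunks
scoreCodes <- function(model, codes, chunk = 1000L) {
  head <- seqHeadOf(model)
  n <- nrow(codes)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    X <- codeToOneHot(codes[s:e, , drop = FALSE])
    out[s:e] <- head$scale * trunkScores(head$trunk, X) + head$offset
  }
  out
}

sampleCodes <- function(n, L, gcFraction = 0.5) {
  probs <- c((1 - gcFraction) / 2, gcFraction / 2, gcFraction / 2,
             (1 - gcFraction) / 2)
  matrix(sample(1:4, n * L, replace = TRUE, prob = probs), n, L)
}

#' In-silico motif multiplicity scan
#'
#' Generates random background sequences (default composition A/T = 0.5,
#' G/C = 0.5), inserts the requested number of non-overlapping k-mer
#' instances at uniform random positions (IUPAC positions resolved per
#' instance), and scores each sequence with the model's sequence head. The
#' score distribution per multiplicity shows whether the network uses motif
#' count as a score-driving predictor.
#'
#' @param model Model with a sequence head.
#' @param kmer Motif to insert (default "CAGSTG").
#' @param counts Multiplicities to test (default 1:5; include 0 for a
#'   background control).
#' @param n Sequences per multiplicity (default 10000).
#' @param length Sequence length in bp (default 500).
#' @param gcFraction Background G+C fraction (default 0.5).
#' @param seed Seed for sequence generation.
#' @return data.frame (count, score), n rows per multiplicity.
#' @export
motifMultiplicityScan <- function(model, kmer = "CAGSTG", counts = 1:5,
                                  n = 10000L, length = 500L,
                                  gcFraction = 0.5, seed = 1L) {
  kl <- nchar(kmer)
  maxCount <- max(counts)
  if (maxCount * kl > length)
    stop("cannot fit ", maxCount, " non-overlapping ", kl, "-mers in ",
         length, " bp")
  base <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  withSeed(seed, {
    out <- lapply(counts, function(cc) {
      codes <- sampleCodes(n, length, gcFraction)
      if (cc > 0) {
        for (i in seq_len(n)) {
          placed <- integer(0)
          while (length(placed) < cc) {
            cand <- sample.int(length - kl + 1L, 1L)
            if (!length(placed) || all(abs(placed - cand) >= kl))
              placed <- c(placed, cand)
          }
          for (p in placed)
            codes[i, p:(p + kl - 1L)] <- base[resolveIupac(kmer)]
        }
      }
      data.frame(count = cc, score = scoreCodes(model, codes))
    })
    do.call(rbind, out)
  })
}

#' Flanking-nucleotide scan around a core motif
#'
#' Embeds the core k-mer (every resolution of its IUPAC positions) flanked
#' by every combination of \code{flankLen} explicit nucleotides on each side
#' into the uniform-composition reference sequence (all positions 0.25), and
#' scores each variant with the sequence head. Fractional one-hot inputs are
#' legal model inputs by design. The unmodified reference is scored as the
#' \code{"background"} row.
#'
#' @param model Model with a sequence head.
#' @param core IUPAC core motif (default "CAGSTG").
#' @param flankLen Explicit flank length per side (default 2).
#' @param maxVariants Safety cap on the variant table size (default 8192).
#' @return data.frame (variant, left, core, right, score), background first.
#' @export
flankScan <- function(model, core = "CAGSTG", flankLen = 2L,
                      maxVariants = 8192L) {
  head <- seqHeadOf(model)
  L <- head$trunk$config$windowWidth %||% 500L
  bases <- c("A", "C", "G", "T")
  coreChars <- strsplit(toupper(core), "")[[1]]
  opts <- lapply(coreChars, function(ch) iupacTable[[ch]])
  coreVariants <- apply(expand.grid(opts, stringsAsFactors = FALSE), 1,
                        paste, collapse = "")
  flanks <- apply(expand.grid(rep(list(bases), flankLen),
                              stringsAsFactors = FALSE), 1,
                  paste, collapse = "")
  grid <- expand.grid(left = flanks, core = coreVariants, right = flanks,
                      stringsAsFactors = FALSE)
  if (nrow(grid) > maxVariants)
    stop("flank scan would produce ", nrow(grid), " variants (cap ",
         maxVariants, ")")
  base <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  ins <- paste0(grid$left, grid$core, grid$right)
  w <- nchar(ins[1])
  at <- (L - w) %/% 2L                    # 0-based insert offset
  bg <- uniformBaseline(L)
  scoreVariant <- function(s) {
    x <- bg
    codes <- base[strsplit(s, "")[[1]]]
    x[(at + 1L):(at + w), ] <- 0
    x[cbind((at + 1L):(at + w), codes)] <- 1
    x
  }
  scoreBatch <- function(mats) {
    X <- array(0, c(length(mats), L, 4))
    for (i in seq_along(mats)) X[i, , ] <- mats[[i]]
    head$scale * trunkScores(head$trunk, X) + head$offset
  }
  scores <- numeric(nrow(grid))
  for (s in seq(1L, nrow(grid), by = 256L)) {
    e <- min(s + 255L, nrow(grid))
    scores[s:e] <- scoreBatch(lapply(ins[s:e], scoreVariant))
  }
  bgScore <- scoreBatch(list(bg))
  rbind(data.frame(variant = "background", left = "", core = "", right = "",
                   score = bgScore),
        data.frame(variant = sprintf("%s|%s|%s", grid$left, grid$core,
                                     grid$right),
                   left = grid$left, core = grid$core, right = grid$right,
                   score = scores))
}
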