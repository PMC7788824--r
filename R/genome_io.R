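#' Read a genome FASTA
#'
#' Reads a multi-record FASTA, uppercases all sequences, and rejects any
#' character outside A/C/G/T/N, naming the offending record and offset.
#'
#' @param path Path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}, one entry per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA", "acgtACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  if (length(genome) == 0) stop("no records in FASTA: ", path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names in FASTA: ", path)
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  for (i in seq_along(genome)) {
    bad <- regexpr("[^ACGTN]", as.character(genome[[i]]))
    if (bad > 0)
      stop("illegal character '", substr(as.character(genome[[i]]), bad, bad),
           "' in record '", names(genome)[i], "' at offset ", bad)
  }
  genome
}

#' Read point binding events with p-values
#'
#' Accepts either a headered TSV (columns chrom, position, pvalue; position is
#' a 0-based point coordinate) or, with \code{dialect = "bed"}, a 6-column BED
#' whose score field holds the p-value (the event point is the interval
#' midpoint). Events are split by the significance threshold: p <= pThreshold
#' is significant (the boundary is inclusive).
#'
#' @param path Input file.
#' @param pThreshold Significance cutoff on the p-value (default 0.001).
#' @param dialect "tsv" (default) or "bed".
#' @param genome Optional \link[Biostrings]{DNAStringSet}; if given, events on
#'   unknown chromosomes or out of bounds are an error.
#' @return A \linkS4class{PeakSet}.
#' @export
readPeaks <- function(path, pThreshold = 0.001, dialect = c("tsv", "bed"),
                      genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !nzchar(first)) {
    tab <- data.frame(chrom = character(0), position = integer(0),
                      pvalue = numeric(0))
  } else if (dialect == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    names(tab)[1:3] <- c("chrom", "position", "pvalue")
  } else {
    bed <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 5) stop("BED dialect requires >= 5 columns")
    tab <- data.frame(chrom = bed[[1]],
                      position = floor((bed[[2]] + bed[[3]]) / 2),
                      pvalue = as.numeric(bed[[5]]))
  }
  makePeakSet(tab$chrom, tab$position, tab$pvalue, pThreshold, genome)
}

#' @rdname readPeaks
#' @param chrom,position,pvalue Event fields (position 0-based).
#' @export
makePeakSet <- function(chrom, position, pvalue, pThreshold = 0.001,
                        genome = NULL) {
  if (any(!is.finite(pvalue)) || any(pvalue < 0 | pvalue > 1))
    stop("p-values must lie in [0, 1]")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
      stop("events on chromosomes absent from the genome: ",
           paste(unknown, collapse = ", "))
    lens <- Biostrings::width(genome)[match(chrom, names(genome))]
    if (any(position < 0 | position >= lens))
      stop("event positions out of chromosome bounds")
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = position + 1L, width = 1L),
                               pvalue = as.numeric(pvalue))
  if (!is.null(genome))
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)[
      match(GenomeInfoDb::seqlevels(gr), names(genome))]
  methods::new("PeakSet", events = gr, pThreshold = pThreshold)
}

#' @rdname readPeaks
#' @param x A PeakSet.
#' @export
significantEvents <- function(x) x@events[x@events$pvalue <= x@pThreshold]

#' @rdname readPeaks
#' @export
nonSignificantEvents <- function(x) x@events[x@events$pvalue > x@pThreshold]

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", length(object@events), "events (",
      length(significantEvents(object)), "significant at p <=",
      object@pThreshold, ")\n")
})

#' Read a bedGraph coverage track
#'
#' Imports a 4-column bedGraph (0-based half-open) as per-base counts.
#'
#' @param path bedGraph file.
#' @param genome \link[Biostrings]{DNAStringSet} supplying chromosome lengths.
#' @param replicate Replicate identifier stored with the track.
#' @return A \linkS4class{CoverageTrack}.
#' @export
readBedGraph <- function(path, genome, replicate = basename(path)) {
  if (!file.exists(path)) stop("bedGraph not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  unknown <- setdiff(GenomeInfoDb::seqlevels(gr), names(sl))
  if (length(unknown))
    stop("bedGraph chromosomes absent from genome: ",
         paste(unknown, collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  cov <- GenomicRanges::coverage(gr, weight = "score")
  coverageTrack(cov, replicate = replicate)
}

#' @rdname readBedGraph
#' @param cov An RleList of per-base counts.
#' @export
coverageTrack <- function(cov, replicate = "rep1") {
  tot <- sum(vapply(cov, function(r) sum(as.numeric(runValue(r)) *
                                           runLength(r)), numeric(1)))
  methods::new("CoverageTrack", cov = cov, replicate = replicate,
               totalTags = tot)
}

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack '", object@replicate, "': ",
      length(object@cov), " chromosomes, ",
      format(object@totalTags, big.mark = ","), " total tags\n", sep = "")
})

#' Tile a genome into fixed-width windows
#'
#' Windows start at 0, advance by \code{step}, and any final partial window
#' is dropped. \code{step = width} gives the non-overlapping test tiling;
#' smaller steps give the overlapping training tiling. Chromosomes shorter
#' than \code{width} are skipped with a warning. Coordinates follow the BED
#' convention internally (the returned GRanges is 1-based as usual in R).
#'
#' @param genome \link[Biostrings]{DNAStringSet} or named vector of
#'   chromosome lengths.
#' @param width Window width in bp (default 500).
#' @param step Offset between successive window starts (default \code{width}).
#' @return \link[GenomicRanges]{GRanges} ordered by (chrom, start).
#' @export
makeWindows <- function(genome, width = 500L, step = width) {
  stopifnot(step >= 1, width >= 1)
  lens <- if (is.numeric(genome)) genome else
    stats::setNames(Biostrings::width(genome), names(genome))
  out <- list()
  for (chrom in names(lens)) {
    if (lens[[chrom]] < width) {
      warning("chromosome ", chrom, " (", lens[[chrom]],
              " bp) shorter than window width ", width, "; skipped")
      next
    }
    starts <- seq.int(0L, lens[[chrom]] - width, by = step)
    out[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = starts + 1L, width = width))
  }
  if (!length(out))
    return(GenomicRanges::GRanges())
  gr <- suppressWarnings(do.call(c, unname(out)))
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Label windows from point binding events
#'
#' A window is \code{bound} if at least one significant event point falls in
#' [start, end); \code{ambiguous} if it contains only non-significant events;
#' \code{unbound} otherwise. Precedence: bound > ambiguous > unbound.
#'
#' @param windows \link[GenomicRanges]{GRanges} of windows.
#' @param peaks A \linkS4class{PeakSet}.
#' @return Factor with levels unbound, bound, ambiguous.
#' @export
labelWindows <- function(windows, peaks) {
  stopifnot(methods::is(peaks, "PeakSet"))
  lab <- factor(rep("unbound", length(windows)),
                levels = c("unbound", "bound", "ambiguous"))
  hitAmb <- IRanges::overlapsAny(windows, nonSignificantEvents(peaks))
  lab[hitAmb] <- "ambiguous"
  hitSig <- IRanges::overlapsAny(windows, significantEvents(peaks))
  lab[hitSig] <- "bound"
  lab
}

#' Tensorize windows into a ChromDataset
#'
#' For each window the DNA sequence is stored as integer codes (one-hot on
#' access, channel order A, C, G, T; N rows all-zero), and each chromatin
#' track is summed into \code{nBins} equal bins, scaled per replicate by
#' \code{normTotal / replicate total tags}, then averaged over replicates and
#' stacked in the declared track order into an N x nBins x k tensor.
#'
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param tracks Named list of tracks; each track is a list of
#'   \linkS4class{CoverageTrack} replicates.
#' @param windows Window \link[GenomicRanges]{GRanges} (all one width).
#' @param nBins Number of bins per window (default 10).
#' @param normTotal Library size to scale each replicate to. The default
#'   10e6 matches genome-scale libraries; pass the mean replicate total to
#'   keep count-like magnitudes on small genomes.
#' @param labels Optional factor from \code{\link{labelWindows}}.
#' @return A \linkS4class{ChromDataset} (accessibility flags unset).
#' @export
tensorize <- function(genome, tracks, windows, nBins = 10L,
                      normTotal = 1e7, labels = NULL) {
  n <- length(windows)
  width <- if (n) GenomicRanges::width(windows)[1] else 500L
  if (n && width %% nBins != 0)
    stop("window width ", width, " not divisible into ", nBins, " bins")
  if (length(tracks) < 1) stop("at least one chromatin track required (k >= 1)")
  binW <- width %/% nBins

  chroms <- as.character(GenomicRanges::seqnames(windows))
  starts <- GenomicRanges::start(windows)
  feat <- array(0, c(n, nBins, length(tracks)))
  for (j in seq_along(tracks)) {
    reps <- tracks[[j]]
    acc <- matrix(0, n, nBins)
    for (rep in reps) {
      if (rep@totalTags <= 0)
        stop("replicate '", rep@replicate, "' of track ", j,
             " has zero total tags")
      sc <- normTotal / rep@totalTags
      for (chrom in unique(chroms)) {
        sel <- which(chroms == chrom)
        if (!chrom %in% names(rep@cov))
          stop("track ", j, " replicate '", rep@replicate,
               "' lacks chromosome ", chrom)
        rle <- rep@cov[[chrom]]
        binStarts <- rep(starts[sel], each = nBins) +
          rep(seq_len(nBins) - 1L, times = length(sel)) * binW
        if (max(binStarts) + binW - 1L > length(rle))
          stop("window out of bounds for track ", j, " on ", chrom)
        v <- IRanges::Views(rle, start = binStarts, width = binW)
        sums <- IRanges::viewSums(v)
        acc[sel, ] <- acc[sel, ] + sc * matrix(sums, ncol = nBins, byrow = TRUE)
      }
    }
    feat[, , j] <- acc / length(reps)
  }

  codes <- matrix(0L, n, width)
  for (chrom in unique(chroms)) {
    sel <- which(chroms == chrom)
    seqs <- Biostrings::extractAt(
      genome[[chrom]],
      IRanges::IRanges(start = starts[sel], width = width))
    codes[sel, ] <- seqToCode(seqs)
  }

  if (is.null(labels))
    labels <- factor(rep(NA_character_, n),
                     levels = c("unbound", "bound", "ambiguous"))
  methods::new("ChromDataset",
               rowRanges = windows, seqCode = codes, chromFeat = feat,
               label = labels, accessible = rep(NA, n),
               trackNames = names(tracks) %||% paste0("track", seq_along(tracks)),
               normTotal = normTotal)
}

#' Assign prior-accessibility flags
#'
#' Peak mode (\code{atacPeaks} given): a window is accessible iff it overlaps
#' an accessibility peak. Coverage mode (\code{trackIndex} given): the mean
#' normalized bin value of the chosen track is computed per window and the
#' windows strictly above the genome-wide nearest-rank quantile \code{q} are
#' flagged; windows tied with a separating threshold are admitted in genomic
#' order until floor(n * (1 - q)) windows are flagged. A constant (e.g.
#' all-zero) track therefore flags nothing.
#'
#' @param dataset A \linkS4class{ChromDataset}.
#' @param atacPeaks Optional \link[GenomicRanges]{GRanges} of accessibility
#'   peaks.
#' @param trackIndex Optional index of the accessibility track in the
#'   dataset's chromatin tensor.
#' @param q Genome-wide quantile for coverage mode (default 0.95).
#' @return The dataset with accessibility flags set.
#' @export
assignAccessibility <- function(dataset, atacPeaks = NULL, trackIndex = NULL,
                                q = 0.95) {
  if (is.null(atacPeaks) && is.null(trackIndex))
    stop("supply either accessibility peaks or a coverage track index")
  if (!is.null(atacPeaks)) {
    acc <- IRanges::overlapsAny(dataset@rowRanges, atacPeaks)
  } else {
    v <- rowMeans(dataset@chromFeat[, , trackIndex, drop = FALSE])
    thr <- nearestRankQuantile(v, q)
    acc <- v > thr
    target <- floor(length(v) * (1 - q))
    short <- target - sum(acc)
    if (short > 0 && thr > min(v)) {
      tied <- which(v == thr)
      acc[tied[seq_len(min(short, length(tied)))]] <- TRUE
    }
  }
  dataset@accessible <- as.logical(acc)
  methods::validObject(dataset)
  dataset
}

#' Split a dataset by chromosome
#'
#' Partitions windows into training, validation, and test sets by
#' chromosome. Ambiguous windows are excluded from all three parts (they are
#' returned separately so the partition is exhaustive).
#'
#' @param dataset A \linkS4class{ChromDataset}.
#' @param testChrom Held-out test chromosome.
#' @param valChrom Validation chromosome (default "chr17").
#' @return List with elements train, val, test, ambiguous.
#' @export
chromosomeSplit <- function(dataset, testChrom, valChrom = "chr17") {
  if (testChrom == valChrom)
    stop("test and validation chromosomes must differ")
  chroms <- as.character(GenomicRanges::seqnames(dataset@rowRanges))
  for (c in c(testChrom, valChrom))
    if (!c %in% chroms) stop("chromosome absent from dataset: ", c)
  amb <- !is.na(dataset@label) & dataset@label == "ambiguous"
  list(train = dataset[!amb & !chroms %in% c(testChrom, valChrom)],
       val = dataset[!amb & chroms == valChrom],
       test = dataset[!amb & chroms == testChrom],
       ambiguous = dataset[amb])
}

## ---- ChromDataset methods ----------------------------------------------

#' @rdname ChromDataset-class
#' @export
setMethod("nWindows", "ChromDataset", function(x) length(x@rowRanges))

#' @rdname ChromDataset-class
#' @export
setMethod("kTracks", "ChromDataset", function(x) length(x@trackNames))

#' @rdname ChromDataset-class
#' @export
setMethod("windowRanges", "ChromDataset", function(x) x@rowRanges)

#' @rdname ChromDataset-class
#' @export
setMethod("bindingLabels", "ChromDataset", function(x) x@label)

#' @rdname ChromDataset-class
#' @export
setReplaceMethod("bindingLabels", "ChromDataset", function(x, value) {
  x@label <- factor(as.character(value),
                    levels = c("unbound", "bound", "ambiguous"))
  methods::validObject(x)
  x
})

#' @rdname ChromDataset-class
#' @export
setMethod("accessibility", "ChromDataset", function(x) x@accessible)

#' @rdname ChromDataset-class
#' @export
setReplaceMethod("accessibility", "ChromDataset", function(x, value) {
  x@accessible <- as.logical(value)
  methods::validObject(x)
  x
})

#' @rdname ChromDataset-class
#' @export
setMethod("seqOneHot", "ChromDataset", function(x, idx) {
  if (missing(idx)) idx <- seq_len(nWindows(x))
  codeToOneHot(x@seqCode[idx, , drop = FALSE])
})

#' @rdname ChromDataset-class
#' @export
setMethod("chromSignal", "ChromDataset", function(x, idx) {
  if (missing(idx)) idx <- seq_len(nWindows(x))
  x@chromFeat[idx, , , drop = FALSE]
})

#' @rdname ChromDataset-class
#' @param i Integer or logical index over windows.
#' @param j,drop Unused.
#' @param ... Unused.
#' @export
setMethod("[", "ChromDataset", function(x, i, j, ..., drop = FALSE) {
  methods::new("ChromDataset",
               rowRanges = x@rowRanges[i],
               seqCode = x@seqCode[i, , drop = FALSE],
               chromFeat = x@chromFeat[i, , , drop = FALSE],
               label = x@label[i],
               accessible = x@accessible[i],
               trackNames = x@trackNames,
               normTotal = x@normTotal)
})

setMethod("show", "ChromDataset", function(object) {
  n <- nWindows(object)
  cat("ChromDataset:", n, "windows x", ncol(object@seqCode), "bp,",
      dim(object@chromFeat)[2], "bins x", kTracks(object), "tracks\n")
  if (n) {
    tab <- table(object@label, useNA = "ifany")
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    if (!all(is.na(object@accessible)))
      cat("  accessible:", sum(object@accessible, na.rm = TRUE), "of", n, "\n")
  }
})

#' Assemble a labeled dataset from genome, tracks and peaks
#'
#' Convenience pipeline: window the genome, label from peaks, tensorize, and
#' assign accessibility (peak mode if \code{atacPeaks} is given, else
#' coverage-quantile mode on \code{atacTrackIndex}).
#'
#' @inheritParams tensorize
#' @param peaks A \linkS4class{PeakSet}.
#' @param step Window step (50 for training tiling, width for test tiling).
#' @param atacPeaks Optional accessibility peak \link[GenomicRanges]{GRanges}.
#' @param atacTrackIndex Track used for coverage-mode accessibility.
#' @param accessQuantile Quantile for coverage mode.
#' @param width Window width.
#' @return A labeled \linkS4class{ChromDataset}.
#' @export
assembleDataset <- function(genome, tracks, peaks, width = 500L, step = width,
                            nBins = 10L, normTotal = NULL, atacPeaks = NULL,
                            atacTrackIndex = 1L, accessQuantile = 0.95) {
  windows <- makeWindows(genome, width = width, step = step)
  labels <- labelWindows(windows, peaks)
  if (is.null(normTotal)) {
    tot <- unlist(lapply(tracks, function(tr)
      vapply(tr, function(r) r@totalTags, numeric(1))))
    normTotal <- mean(tot)
  }
  ds <- tensorize(genome, tracks, windows, nBins = nBins,
                  normTotal = normTotal, labels = labels)
  if (!is.null(atacPeaks))
    assignAccessibility(ds, atacPeaks = atacPeaks)
  else
    assignAccessibility(ds, trackIndex = atacTrackIndex, q = accessQuantile)
}
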