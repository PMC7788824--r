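#' Synthetic-data configuration
#'
#' Defines a multi-chromosome synthetic study: an i.i.d. background genome at
#' a stated GC fraction, IUPAC motifs planted at Poisson-distributed counts in
#' designated 500 bp tiles, accessibility domains with per-track coverage
#' effects and Poisson noise (with replicates differing in depth and noise),
#' and binding labels drawn from a logistic compensation rule
#' \deqn{P(bound) = sigmoid(intercept + wMotif * count + wAccess * access +
#'   wInteraction * count * (1 - access))}
#' so that favorable prior chromatin partially compensates for weaker
#' sequence features: bound tiles in inaccessible chromatin need higher motif
#' multiplicity, which is exactly the structure the latent embedding is
#' expected to recover.
#'
#' Presets: \code{"tiny"} (3 chromosomes x 200 kb, k = 2 informative tracks;
#' the desk-scale study condition, end-to-end trainable on one CPU),
#' \code{"default"} (6 x 300 kb, otherwise as tiny), \code{"chromatin_noise"}
#' (tiny geometry but tracks placed on decoy domains and a binding rule that
#' ignores accessibility -- the synthetic analogue of pairing sequence with a
#' ChIP input control), and \code{"accessible"} (tiny geometry with a binding
#' rule leaving under 10 percent of bound tiles inaccessible, exercising the
#' relaxed sampler path).
#'
#' The default rule weights were fixed once so that roughly 8 percent of
#' tiles are bound and about a third of bound tiles fall in inaccessible
#' chromatin (exercising the matched sampler).
#'
#' @param preset Preset name.
#' @param ... Named overrides of any config field.
#' @return A list of class "SimConfig".
#' @export
simConfig <- function(preset = c("tiny", "default", "chromatin_noise",
                                 "accessible"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    nChroms = 3L, chromLength = 200000L, tileWidth = 500L,
    gcFraction = 0.42,
    motif = "CAGSTG", preferredFlank = NULL, flankProb = 0.7,
    siteRate = 0.25, motifMean = 1.5,
    accessFraction = 0.25, domainWidth = 2000L,
    kTracks = 2L, nReplicates = 2L,
    baseRate = 0.02, domainEffect = c(0.15, 0.10),
    repDepth = c(1, 1.3),
    trackInformative = TRUE,
    intercept = -6.5, wMotif = 1.5, wAccess = 4.0, wInteraction = 0.5,
    ambigRate = 0.05,
    pSigRange = c(1e-8, 1e-3), pNonSigRange = c(1.01e-3, 0.05))
  if (preset == "default") {
    cfg$nChroms <- 6L; cfg$chromLength <- 300000L
  } else if (preset == "chromatin_noise") {
    cfg$nChroms <- 6L; cfg$chromLength <- 300000L
    cfg$trackInformative <- FALSE
    cfg$wAccess <- 0; cfg$wInteraction <- 0; cfg$intercept <- -3.8
  } else if (preset == "accessible") {
    cfg$wAccess <- 6; cfg$wInteraction <- 0
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown SimConfig fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$gcFraction > 0, cfg$gcFraction < 1,
            cfg$siteRate >= 0, cfg$siteRate <= 1,
            cfg$accessFraction > 0, cfg$accessFraction < 1,
            cfg$kTracks >= 1, all(is.finite(unlist(cfg[c(
              "intercept", "wMotif", "wAccess", "wInteraction")]))))
  class(cfg) <- "SimConfig"
  cfg
}

iupacTable <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

resolveIupac <- function(motif) {
  vapply(strsplit(motif, "")[[1]], function(ch) {
    opts <- iupacTable[[ch]]
    if (is.null(opts)) stop("invalid IUPAC code: ", ch)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
}

#' Generate a synthetic genome with planted motifs
#'
#' Background bases are i.i.d. at the configured GC fraction. Each 500 bp
#' tile is designated a motif site with probability \code{siteRate}; a
#' designated tile receives a Poisson(\code{motifMean}) number of
#' non-overlapping motif instances (ambiguous IUPAC positions resolved
#' uniformly per instance; optional preferred flanks applied with probability
#' \code{flankProb}). Uses the current RNG state; seed via
#' \code{\link{simulateDataset}}.
#'
#' @param config A \code{\link{simConfig}}.
#' @return List with \code{genome} (DNAStringSet) and \code{motifTruth}
#'   (data.frame: chrom, start, end (0-based half-open), motifCount).
#' @export
generateGenome <- function(config) {
  w <- config$tileWidth
  motifLen <- nchar(config$motif)
  flank <- config$preferredFlank
  flankLen <- if (is.null(flank)) 0L else nchar(flank$left)
  pad <- motifLen + 2L * flankLen + 2L
  probs <- c(A = (1 - config$gcFraction) / 2, C = config$gcFraction / 2,
             G = config$gcFraction / 2, T = (1 - config$gcFraction) / 2)
  chromNames <- paste0("chrS", seq_len(config$nChroms))
  seqs <- character(config$nChroms)
  truth <- list()
  for (ci in seq_len(config$nChroms)) {
    len <- config$chromLength
    chars <- sample(names(probs), len, replace = TRUE, prob = probs)
    starts0 <- seq.int(0L, len - w, by = w)
    isSite <- stats::rbinom(length(starts0), 1L, config$siteRate) == 1L
    counts <- integer(length(starts0))
    counts[isSite] <- stats::rpois(sum(isSite), config$motifMean)
    for (ti in which(counts > 0L)) {
      m <- counts[ti]
      lo <- starts0[ti] + 20L
      hi <- starts0[ti] + w - 20L - pad
      placed <- integer(0)
      for (tries in seq_len(100L)) {
        cand <- sort(sample(lo:hi, m))
        if (m == 1L || all(diff(cand) >= pad)) { placed <- cand; break }
      }
      if (!length(placed)) {          # fall back to fewer instances
        placed <- lo
        counts[ti] <- 1L
      }
      for (p0 in placed) {
        inst <- resolveIupac(config$motif)
        at <- p0 + flankLen
        chars[(at + 1L):(at + motifLen)] <- inst
        if (flankLen > 0L && stats::runif(1) < config$flankProb) {
          chars[(p0 + 1L):(p0 + flankLen)] <- strsplit(flank$left, "")[[1]]
          chars[(at + motifLen + 1L):(at + motifLen + flankLen)] <-
            strsplit(flank$right, "")[[1]]
        }
      }
    }
    seqs[ci] <- paste(chars, collapse = "")
    truth[[ci]] <- data.frame(chrom = chromNames[ci], start = starts0,
                              end = starts0 + w, motifCount = counts)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chromNames
  list(genome = genome, motifTruth = do.call(rbind, truth))
}

placeDomains <- function(config, chromNames) {
  segLen <- round(config$domainWidth / config$accessFraction)
  out <- list()
  for (chrom in chromNames) {
    nSeg <- config$chromLength %/% segLen
    segStarts <- (seq_len(nSeg) - 1L) * segLen
    offs <- floor(stats::runif(nSeg, 0, segLen - config$domainWidth + 1))
    out[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = segStarts + offs + 1L,
                              width = config$domainWidth))
  }
  suppressWarnings(do.call(c, unname(out)))
}

#' Generate synthetic chromatin tracks and accessibility domains
#'
#' Accessibility domains are placed at the configured genome fraction; each
#' of the k tracks gets per-base Poisson coverage at
#' \code{baseRate + domainEffect[j]} inside its effect domains, with
#' replicates sharing structure but differing in depth and noise. When
#' \code{trackInformative} is FALSE the effect domains are independent decoys,
#' so tracks (and any accessibility labels derived from them) carry no
#' information about binding.
#'
#' @param config A \code{\link{simConfig}}.
#' @param genome The generated \link[Biostrings]{DNAStringSet}.
#' @return List with \code{tracks} (list of k lists of
#'   \linkS4class{CoverageTrack} replicates), \code{accessDomains} (the truth
#'   used by the binding rule), and \code{atacPeaks} (what a peak caller
#'   would report: track 1's effect domains).
#' @export
generateChromatin <- function(config, genome) {
  chromNames <- names(genome)
  accessDomains <- placeDomains(config, chromNames)
  effect <- rep_len(config$domainEffect, config$kTracks)
  depth <- rep_len(config$repDepth, config$nReplicates)
  tracks <- list()
  trackDomains <- list()
  for (j in seq_len(config$kTracks)) {
    dom <- if (config$trackInformative) accessDomains
           else placeDomains(config, chromNames)
    trackDomains[[j]] <- dom
    reps <- list()
    for (r in seq_len(config$nReplicates)) {
      covs <- lapply(chromNames, function(chrom) {
        len <- config$chromLength
        rate <- rep(config$baseRate, len)
        d <- dom[GenomicRanges::seqnames(dom) == chrom]
        for (ii in seq_along(d)) {
          rate[GenomicRanges::start(d)[ii]:GenomicRanges::end(d)[ii]] <-
            config$baseRate + effect[j]
        }
        S4Vectors::Rle(stats::rpois(len, rate * depth[r]))
      })
      names(covs) <- chromNames
      reps[[r]] <- coverageTrack(methods::as(covs, "RleList"),
                                 replicate = paste0("rep", r))
    }
    tracks[[paste0("track", j)]] <- reps
  }
  list(tracks = tracks, accessDomains = accessDomains,
       atacPeaks = trackDomains[[1]])
}

#' Generate binding events from the compensation rule
#'
#' Each 500 bp tile's binding probability follows the logistic rule in
#' \code{\link{simConfig}}; realized labels are Bernoulli draws. Bound tiles
#' emit one significant point event (p log-uniform in the significant range);
#' a configured fraction of unbound tiles -- sampled proportionally to their
#' binding probability, i.e. near-threshold tiles -- emit non-significant
#' events that become ambiguous windows downstream.
#'
#' @param config A \code{\link{simConfig}}.
#' @param motifTruth From \code{\link{generateGenome}}.
#' @param accessDomains From \code{\link{generateChromatin}}.
#' @return List with \code{peaks} (data.frame chrom, position, pvalue) and
#'   \code{truth} (per-tile data.frame with motifCount, accessible, trueProb,
#'   bound).
#' @export
generateBinding <- function(config, motifTruth, accessDomains) {
  mids <- GenomicRanges::GRanges(
    motifTruth$chrom,
    IRanges::IRanges(start = motifTruth$start + config$tileWidth %/% 2L,
                     width = 1L))
  acc <- IRanges::overlapsAny(mids, accessDomains)
  cnt <- motifTruth$motifCount
  eta <- config$intercept + config$wMotif * cnt + config$wAccess * acc +
    config$wInteraction * cnt * (1 - acc)
  p <- stats::plogis(eta)
  if (all(p > 0.99) || all(p < 0.01))
    warning("degenerate binding rule: all-or-none binding probabilities")
  bound <- stats::rbinom(length(p), 1L, p) == 1L
  truth <- data.frame(motifTruth, accessible = acc, trueProb = p,
                      bound = bound)

  nB <- sum(bound)
  jitter <- round(stats::runif(nB, -100, 100))
  sigP <- 10^stats::runif(nB, log10(config$pSigRange[1]),
                          log10(config$pSigRange[2]))
  peaks <- data.frame(
    chrom = motifTruth$chrom[bound],
    position = motifTruth$start[bound] + config$tileWidth %/% 2L + jitter,
    pvalue = sigP)

  unb <- which(!bound)
  nAmb <- round(config$ambigRate * length(unb))
  if (nAmb > 0) {
    pick <- sample(unb, nAmb, prob = p[unb])
    ambP <- 10^stats::runif(nAmb, log10(config$pNonSigRange[1]),
                            log10(config$pNonSigRange[2]))
    peaks <- rbind(peaks, data.frame(
      chrom = motifTruth$chrom[pick],
      position = motifTruth$start[pick] + config$tileWidth %/% 2L,
      pvalue = ambP))
  }
  ord <- order(peaks$chrom, peaks$position)
  list(peaks = peaks[ord, , drop = FALSE], truth = truth)
}

#' Simulate a complete study in memory
#'
#' Runs genome, chromatin, and binding generation under one seed and returns
#' all components plus truth tables. Fully deterministic: the same seed gives
#' identical objects.
#'
#' @param config A \code{\link{simConfig}}.
#' @param seed Integer seed.
#' @return A list of class "SeqchromSim": genome, motifTruth, tracks,
#'   accessDomains, atacPeaks, peaks, truth, peakSet, config, seed.
#' @export
simulateDataset <- function(config = simConfig(), seed = 1L) {
  withSeed(seed, {
    g <- generateGenome(config)
    chr <- generateChromatin(config, g$genome)
    b <- generateBinding(config, g$motifTruth, chr$accessDomains)
    out <- c(g, chr, b,
             list(peakSet = makePeakSet(b$peaks$chrom, b$peaks$position,
                                        b$peaks$pvalue, genome = g$genome),
                  config = config, seed = as.integer(seed)))
    class(out) <- "SeqchromSim"
    out
  })
}

#' Build a ChromDataset from an in-memory simulation
#'
#' @param sim From \code{\link{simulateDataset}}.
#' @param step Window step (50 for training tiling, window width for testing).
#' @param width Window width.
#' @param normTotal Library size target; default (NULL) uses the mean
#'   replicate total so normalized bins keep count-like magnitudes on small
#'   genomes.
#' @return A labeled \linkS4class{ChromDataset} with accessibility flags from
#'   the simulated accessibility peaks.
#' @export
datasetFromSim <- function(sim, step = 500L, width = 500L, normTotal = NULL) {
  assembleDataset(sim$genome, sim$tracks, sim$peakSet, width = width,
                  step = step, normTotal = normTotal,
                  atacPeaks = sim$atacPeaks)
}

#' Train/validation/test datasets from a simulation
#'
#' Training windows use the overlapping tiling (step 50), validation and test
#' windows the non-overlapping tiling, split by chromosome with ambiguous
#' windows excluded.
#'
#' @inheritParams datasetFromSim
#' @param testChrom,valChrom Held-out chromosomes.
#' @param trainStep Step for the training tiling (default 50).
#' @return List with train, val, test \linkS4class{ChromDataset}s.
#' @export
simSplit <- function(sim, testChrom, valChrom, trainStep = 50L, width = 500L) {
  dsTrain <- datasetFromSim(sim, step = trainStep, width = width)
  dsTile <- datasetFromSim(sim, step = width, width = width)
  a <- chromosomeSplit(dsTrain, testChrom, valChrom)
  b <- chromosomeSplit(dsTile, testChrom, valChrom)
  list(train = a$train, val = b$val, test = b$test)
}

rleToBedGraph <- function(rle, chrom) {
  ends <- cumsum(runLength(rle))
  starts <- c(0L, ends[-length(ends)])
  data.frame(chrom = chrom, start = starts, end = ends,
             value = runValue(rle))
}

#' Write a synthetic fixture to disk
#'
#' Emits the exact dialects the readers consume: genome FASTA, peak TSV
#' (chrom, position, pvalue), one bedGraph per track replicate, accessibility
#' peak BED, per-tile truth TSV, and a JSON manifest recording preset, seed
#' and file list. Output is byte-identical under a fixed seed.
#'
#' @param preset Preset name passed to \code{\link{simConfig}}, or a full
#'   SimConfig.
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
generateFixture <- function(preset = "tiny", seed = 1L, outdir) {
  config <- if (inherits(preset, "SimConfig")) preset else simConfig(preset)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateDataset(config, seed)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                peaks = file.path(outdir, "peaks.tsv"),
                atac = file.path(outdir, "atac_peaks.bed"),
                truth = file.path(outdir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths$genome, width = 80L)
  pk <- sim$peaks
  pk$pvalue <- sprintf("%.6e", pk$pvalue)
  utils::write.table(pk, paths$peaks, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(sim$atacPeaks)),
                    start = GenomicRanges::start(sim$atacPeaks) - 1L,
                    end = GenomicRanges::end(sim$atacPeaks))
  utils::write.table(bed, paths$atac, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tr <- sim$truth
  tr$trueProb <- sprintf("%.6f", tr$trueProb)
  utils::write.table(tr, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  trackFiles <- character(0)
  for (j in seq_along(sim$tracks)) {
    for (r in seq_along(sim$tracks[[j]])) {
      f <- file.path(outdir, sprintf("track%d_rep%d.bedGraph", j, r))
      rows <- do.call(rbind, lapply(names(sim$tracks[[j]][[r]]@cov), function(ch)
        rleToBedGraph(sim$tracks[[j]][[r]]@cov[[ch]], ch)))
      utils::write.table(rows, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      trackFiles <- c(trackFiles, f)
    }
  }
  paths$tracks <- trackFiles
  writeManifest(file.path(outdir, "manifest.json"),
                list(preset = config$preset, seed = as.integer(seed),
                     kTracks = config$kTracks,
                     nReplicates = config$nReplicates,
                     chromosomes = names(sim$genome),
                     chromLength = config$chromLength,
                     files = lapply(paths, basename)),
                timestamp = FALSE)
  invisible(paths)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by \code{\link{generateFixture}}.
#' @return A list with genome, peakSet, tracks, atacPeaks, truth, manifest.
#' @export
readFixture <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  genome <- readGenome(file.path(dir, "genome.fa"))
  peakSet <- readPeaks(file.path(dir, "peaks.tsv"), genome = genome)
  tracks <- list()
  for (j in seq_len(man$kTracks)) {
    reps <- list()
    for (r in seq_len(man$nReplicates)) {
      f <- file.path(dir, sprintf("track%d_rep%d.bedGraph", j, r))
      reps[[r]] <- readBedGraph(f, genome, replicate = paste0("rep", r))
    }
    tracks[[paste0("track", j)]] <- reps
  }
  atacBed <- utils::read.table(file.path(dir, "atac_peaks.bed"), sep = "\t")
  atacPeaks <- GenomicRanges::GRanges(
    atacBed[[1]], IRanges::IRanges(start = atacBed[[2]] + 1L, end = atacBed[[3]]))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t")
  list(genome = genome, peakSet = peakSet, tracks = tracks,
       atacPeaks = atacPeaks, truth = truth, manifest = man)
}
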