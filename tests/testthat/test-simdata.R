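# The generator's marginals were calibrated once (see the methods vignette);
# these tests check the declared structure, determinism, and closed forms.

test_that("simulation is fully deterministic under a seed", {
  cfg <- simConfig("tiny", chromLength = 20000L)
  s1 <- simulateDataset(cfg, seed = 7L)
  s2 <- simulateDataset(cfg, seed = 7L)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$peaks, s2$peaks)
  s3 <- simulateDataset(cfg, seed = 8L)
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("fixtures are byte-identical under a fixed seed", {
  cfg <- simConfig("tiny", chromLength = 20000L)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  generateFixture(cfg, seed = 3L, outdir = d1)
  generateFixture(cfg, seed = 3L, outdir = d2)
  files <- list.files(d1)
  expect_true(all(c("genome.fa", "peaks.tsv", "atac_peaks.bed", "truth.tsv",
                    "manifest.json") %in% files))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
})

test_that("fixture round-trip preserves the study", {
  cfg <- simConfig("tiny", chromLength = 20000L)
  d <- file.path(tempdir(), "fx-rt")
  generateFixture(cfg, seed = 3L, outdir = d)
  sim <- simulateDataset(cfg, seed = 3L)
  fx <- readFixture(d)
  expect_identical(as.character(fx$genome), as.character(sim$genome))
  expect_equal(fx$truth$motifCount, sim$truth$motifCount)
  expect_equal(length(significantEvents(fx$peakSet)),
               length(significantEvents(sim$peakSet)))
  expect_equal(fx$manifest$preset, "tiny")
  # tracks reload to the same per-base coverage
  expect_identical(as.numeric(fx$tracks[[1]][[1]]@cov[[1]]),
                   as.numeric(sim$tracks[[1]][[1]]@cov[[1]]))
})

test_that("background GC fraction matches the target within 3 s.e.", {
  sim <- quickSim()
  seqChars <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  gc <- mean(seqChars %in% c("G", "C"))
  n <- length(seqChars)
  se <- sqrt(0.42 * 0.58 / n)
  # planted motifs perturb composition slightly; allow 3 s.e. + 1% slack
  expect_lt(abs(gc - 0.42), 3 * se + 0.01)
})

test_that("planted motif counts are recovered by the k-mer counter", {
  sim <- quickSim()
  truth <- sim$truth[sim$truth$chrom == "chrS1", ]
  tiles <- Biostrings::extractAt(
    sim$genome[["chrS1"]],
    IRanges::IRanges(start = truth$start + 1L, end = truth$end))
  counts <- countIupacKmer(as.character(tiles), "CAGSTG")
  # every planted instance is present; background can add occurrences
  expect_true(all(counts >= truth$motifCount))
  expect_gt(cor(counts, truth$motifCount), 0.9)
})

test_that("realized binding matches the logistic rule within MC error", {
  sim <- cached("margSim", {
    simulateDataset(simConfig("tiny", nChroms = 5L), seed = 55L)
  })
  tr <- sim$truth
  expect_equal(tr$trueProb,
               plogis(-6.5 + 1.5 * tr$motifCount + 4 * tr$accessible +
                        0.5 * tr$motifCount * (1 - tr$accessible)),
               tolerance = 1e-12)
  # realized bound fraction within 4 sigma of the mean true probability
  nT <- nrow(tr)
  se <- sqrt(sum(tr$trueProb * (1 - tr$trueProb))) / nT
  expect_lt(abs(mean(tr$bound) - mean(tr$trueProb)), 4 * se)
  # accessibility raises binding at matched motif count
  for (k in 0:2) {
    sel <- tr$motifCount == k
    pAcc <- mean(tr$bound[sel & tr$accessible])
    pIn <- mean(tr$bound[sel & !tr$accessible])
    expect_gt(pAcc, pIn)
  }
})

test_that("compensation: bound-inaccessible tiles carry more motifs", {
  sim <- cached("margSim", {
    simulateDataset(simConfig("tiny", nChroms = 5L), seed = 55L)
  })
  tr <- sim$truth
  expect_gt(mean(tr$motifCount[tr$bound & !tr$accessible]),
            mean(tr$motifCount[tr$bound & tr$accessible]))
})

test_that("the chromatin_noise preset decouples tracks from binding", {
  cfg <- simConfig("chromatin_noise")
  expect_false(cfg$trackInformative)
  expect_equal(cfg$wAccess, 0)
  expect_equal(cfg$wInteraction, 0)
  sim <- cached("noiseSimSmall", {
    simulateDataset(simConfig("chromatin_noise", nChroms = 3L,
                              chromLength = 100000L), seed = 56L)
  })
  tr <- sim$truth
  # binding probability ignores accessibility entirely
  expect_equal(length(unique(tapply(tr$trueProb, tr$motifCount,
                                    function(v) diff(range(v))))), 1L)
  expect_true(all(tapply(tr$trueProb, tr$motifCount,
                         function(v) diff(range(v))) == 0))
  # permutation test: no association between accessibility and binding
  obs <- abs(mean(tr$bound[tr$accessible]) - mean(tr$bound[!tr$accessible]))
  set.seed(57)
  null <- replicate(200, {
    p <- sample(tr$accessible)
    abs(mean(tr$bound[p]) - mean(tr$bound[!p]))
  })
  expect_gt(mean(null >= obs), 0.01)
})

test_that("training window count follows the tiling formula", {
  sim <- quickSim()   # 3 chromosomes x 60 kb
  ds <- datasetFromSim(sim, step = 50L)
  expect_equal(nWindows(ds), 3 * ((60000 - 500) / 50 + 1))
  dsTile <- datasetFromSim(sim, step = 500L)
  expect_equal(nWindows(dsTile), 3 * (60000 / 500))
})

test_that("dataset labels agree with simulated truth at tile resolution", {
  sim <- quickSim()
  ds <- datasetFromSim(sim, step = 500L)
  lab <- bindingLabels(ds)
  tr <- sim$truth
  # every bound tile whose peak stayed in-tile labels its window bound;
  # peak jitter is +/- 100 bp so at least the unjittered expectations hold
  boundFrac <- mean(lab == "bound")
  expect_gt(boundFrac, 0.5 * mean(tr$bound))
  expect_lt(boundFrac, 2 * mean(tr$bound) + 0.05)
  # ambiguous windows exist at the configured rate
  expect_gt(mean(lab == "ambiguous"), 0)
})

test_that("simSplit keeps chromosomes disjoint across parts", {
  sp <- quickSplit()
  chromOf <- function(d)
    unique(as.character(GenomicRanges::seqnames(windowRanges(d))))
  expect_false("chrS1" %in% chromOf(sp$train))
  expect_false("chrS2" %in% chromOf(sp$train))
  expect_equal(chromOf(sp$val), "chrS2")
  expect_equal(chromOf(sp$test), "chrS1")
})

test_that("degenerate binding rules are flagged", {
  cfg <- simConfig("tiny", chromLength = 20000L, intercept = 50)
  expect_warning(simulateDataset(cfg, seed = 1L), "degenerate")
})

test_that("unknown config fields are rejected", {
  expect_error(simConfig("tiny", noSuchField = 1), "unknown")
})
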