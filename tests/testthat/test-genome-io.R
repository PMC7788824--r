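writeFasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

test_that("readGenome uppercases and validates the alphabet", {
  g <- readGenome(writeFasta(c(">chrA desc", "acgtnACGTN")))
  expect_equal(names(g), "chrA")
  expect_equal(as.character(g[[1]]), "ACGTNACGTN")

  bad <- writeFasta(c(">chrA", "ACGT", ">chrB", "ACRT"))
  expect_error(readGenome(bad), "chrB.*offset 3|'R'")
  expect_error(readGenome(writeFasta(c(">x", "AC", ">x", "GG"))), "duplicate")
  expect_error(readGenome(tempfile()), "not found")
})

test_that("peak reading splits events at the inclusive threshold", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tpvalue",
               "chr1\t100\t1e-5",
               "chr1\t200\t0.001",
               "chr1\t300\t0.0011",
               "chr1\t400\t0.04"), f)
  ps <- readPeaks(f)
  expect_s4_class(ps, "PeakSet")
  # p = 0.001 is significant (boundary inclusive), p = 0.0011 is not
  expect_equal(GenomicRanges::start(significantEvents(ps)), c(101L, 201L))
  expect_equal(GenomicRanges::start(nonSignificantEvents(ps)), c(301L, 401L))
})

test_that("makePeakSet validates p-values and genome bounds", {
  expect_error(makePeakSet("chr1", 10, 1.5), "\\[0, 1\\]")
  expect_error(makePeakSet("chr1", 10, -0.1), "\\[0, 1\\]")
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_error(makePeakSet("chr2", 1, 0.5, genome = g), "absent")
  expect_error(makePeakSet("chr1", 8, 0.5, genome = g), "out of")
  expect_silent(makePeakSet("chr1", 7, 0.5, genome = g))
})

test_that("makeWindows matches a brute-force enumeration", {
  lens <- c(chrA = 1234L, chrB = 500L, chrC = 2000L)
  w <- makeWindows(lens, width = 500L, step = 300L)
  ref <- list()
  for (ch in names(lens)) {
    starts <- seq(0L, lens[[ch]] - 500L, by = 300L)
    starts <- starts[starts + 500L <= lens[[ch]]]
    ref[[ch]] <- starts
  }
  got <- split(GenomicRanges::start(w) - 1L,
               as.character(GenomicRanges::seqnames(w)))
  expect_equal(got[names(lens)], ref)
  # non-overlapping tiling count identity
  w2 <- makeWindows(lens, width = 500L)
  expect_equal(length(w2), sum(lens %/% 500L))
  expect_warning(makeWindows(c(tiny = 300L), width = 500L), "skipped")
})

test_that("labelWindows applies bound > ambiguous > unbound precedence", {
  win <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 501, 1001, 1501), width = 500))
  ps <- makePeakSet(chrom = c("chr1", "chr1", "chr1"),
                    position = c(100, 600, 620),
                    pvalue = c(1e-5, 0.01, 1e-6))
  lab <- labelWindows(win, ps)
  # window 2 holds a significant and a non-significant event -> bound wins
  expect_equal(as.character(lab), c("bound", "bound", "unbound", "unbound"))
  ps2 <- makePeakSet("chr1", 1200, 0.01)
  expect_equal(as.character(labelWindows(win, ps2))[3], "ambiguous")
})

# minimal one-chromosome study for tensorize oracles
toyCoverage <- function(values, chrom = "chrZ") {
  covs <- list(S4Vectors::Rle(values))
  names(covs) <- chrom
  coverageTrack(methods::as(covs, "RleList"))
}

test_that("tensorize bins, normalizes, and averages replicates correctly", {
  len <- 100L
  genome <- Biostrings::DNAStringSet(
    c(chrZ = paste(rep("ACGTN", 20), collapse = "")))
  v1 <- rep(1, len); v2 <- rep(2, len)   # rep2 = doubled depth
  tracks <- list(atac = list(toyCoverage(v1), toyCoverage(v2)))
  win <- makeWindows(genome, width = 50L, step = 50L)
  ds <- tensorize(genome, tracks, win, nBins = 10L, normTotal = 100)
  # rep1 total 100 -> scale 1; rep2 total 200 -> scale 0.5; both yield 5/bin
  expect_equal(dim(ds@chromFeat), c(2, 10, 1))
  expect_true(all(abs(ds@chromFeat - 5) < 1e-12))
  # sequence codes follow the ACGTN cycle; N encodes as 0
  expect_equal(ds@seqCode[1, 1:5], c(1L, 2L, 3L, 4L, 0L))
  oh <- seqOneHot(ds, 1L)
  expect_equal(oh[1, 5, ], rep(0, 4))          # N row all-zero
  expect_equal(oh[1, 1, ], c(1, 0, 0, 0))
  expect_error(tensorize(genome, list(), win), "at least one")
  expect_error(tensorize(genome, tracks, win, nBins = 7L), "divisible")
})

test_that("replicate depth does not change normalized features", {
  len <- 200L
  set.seed(21)
  base <- rpois(len, 3)
  genome <- Biostrings::DNAStringSet(
    c(chrZ = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")))
  win <- makeWindows(genome, width = 50L, step = 50L)
  d1 <- tensorize(genome, list(t = list(toyCoverage(base))), win,
                  normTotal = 1000)
  d2 <- tensorize(genome, list(t = list(toyCoverage(base * 4))), win,
                  normTotal = 1000)
  expect_equal(d1@chromFeat, d2@chromFeat, tolerance = 1e-12)
})

test_that("coverage-mode accessibility uses the strict nearest-rank quantile", {
  ds <- toyDataset(rep("unbound", 20), rep(NA, 20), k = 1L)
  v <- seq_len(20) / 20
  ds@chromFeat <- array(rep(v, 10), c(20, 10, 1))   # per-window mean = v
  out <- assignAccessibility(ds, trackIndex = 1L, q = 0.75)
  # strictly above the 0.75 nearest-rank quantile (v = 15/20): windows 16..20
  expect_equal(which(accessibility(out)), 16:20)
  # a constant track flags nothing
  ds@chromFeat <- array(1, c(20, 10, 1))
  expect_equal(sum(accessibility(assignAccessibility(ds, trackIndex = 1L))), 0)
  expect_error(assignAccessibility(ds), "supply either")
})

test_that("peak-mode accessibility flags overlapping windows", {
  ds <- toyDataset(rep("unbound", 5), rep(NA, 5), width = 100L)
  peaks <- windowRanges(ds)[c(2, 4)]
  out <- assignAccessibility(ds, atacPeaks = peaks)
  expect_equal(accessibility(out), c(FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("chromosomeSplit partitions exhaustively and drops ambiguous", {
  labels <- rep(c("unbound", "bound", "ambiguous"), times = c(6, 4, 2))
  chrom <- rep(c("c1", "c2", "c3"), each = 4)
  ds <- toyDataset(labels, rep(TRUE, 12), chrom = chrom)
  sp <- chromosomeSplit(ds, testChrom = "c1", valChrom = "c2")
  tot <- nWindows(sp$train) + nWindows(sp$val) + nWindows(sp$test) +
    nWindows(sp$ambiguous)
  expect_equal(tot, 12L)
  for (part in list(sp$train, sp$val, sp$test))
    expect_false(any(bindingLabels(part) == "ambiguous"))
  expect_equal(unique(as.character(
    GenomicRanges::seqnames(windowRanges(sp$test)))), "c1")
  expect_equal(unique(as.character(
    GenomicRanges::seqnames(windowRanges(sp$val)))), "c2")
  expect_false(any(as.character(
    GenomicRanges::seqnames(windowRanges(sp$train))) %in% c("c1", "c2")))
  expect_error(chromosomeSplit(ds, "c1", "c1"), "must differ")
  expect_error(chromosomeSplit(ds, "c9", "c2"), "absent")
})

test_that("ChromDataset round-trips through the on-disk container", {
  ds <- toyDataset(rep(c("bound", "unbound"), 3), rep(c(TRUE, FALSE), 3),
                   k = 2L)
  dir <- file.path(tempdir(), "ds-roundtrip")
  writeChromDataset(ds, dir)
  back <- readChromDataset(dir)
  expect_equal(back@seqCode, ds@seqCode)
  expect_equal(back@chromFeat, ds@chromFeat, tolerance = 1e-7)
  expect_equal(bindingLabels(back), bindingLabels(ds))
  expect_equal(accessibility(back), accessibility(ds))
  expect_equal(as.character(GenomicRanges::seqnames(windowRanges(back))),
               as.character(GenomicRanges::seqnames(windowRanges(ds))))
  expect_equal(back@trackNames, ds@trackNames)
})

test_that("dataset subsetting keeps slots aligned", {
  ds <- toyDataset(rep(c("bound", "unbound"), 4), rep(c(TRUE, FALSE), 4))
  sub <- ds[c(2, 5)]
  expect_equal(nWindows(sub), 2L)
  expect_equal(bindingLabels(sub), bindingLabels(ds)[c(2, 5)])
  expect_equal(sub@seqCode, ds@seqCode[c(2, 5), ])
  expect_equal(sub@chromFeat, ds@chromFeat[c(2, 5), , , drop = FALSE])
})

test_that("bedGraph coverage import matches hand-computed per-base counts", {
  g <- Biostrings::DNAStringSet(c(chrQ = paste(rep("A", 30), collapse = "")))
  f <- tempfile(fileext = ".bedGraph")
  writeLines(c("chrQ\t0\t10\t2", "chrQ\t15\t20\t3"), f)
  tr <- readBedGraph(f, g)
  v <- as.numeric(tr@cov[["chrQ"]])
  expect_equal(v, c(rep(2, 10), rep(0, 5), rep(3, 5), rep(0, 10)))
  expect_equal(tr@totalTags, 35)
})
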