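test_that("integrated gradients is exact for a linear head", {
  L <- 30L
  model <- linearSeqModel(L, seed = 61L, w = 1.7, b = 0.4)
  set.seed(62)
  x <- seqchrom:::codeToOneHot(matrix(sample(1:4, L, TRUE), 1, L))[1, , ]
  tr <- integratedGradients(model, x, m = 16L)
  expected <- (x - seqchrom:::uniformBaseline(L)) * linearModelGrad(model)
  expect_lt(max(abs(tr@perChannel - expected)), 1e-10)
  expect_equal(tr@perPosition, rowSums(expected), tolerance = 1e-10)
  # completeness is exact for a linear head
  expect_lt(completenessResidual(tr), 1e-10)
})

test_that("attribution at the baseline itself is identically zero", {
  model <- linearSeqModel(20L)
  bl <- seqchrom:::uniformBaseline(20L)
  tr <- integratedGradients(model, bl, m = 8L)
  expect_true(all(tr@perChannel == 0))
  expect_equal(tr@fx, tr@fBaseline)
})

test_that("completeness residual meets tolerance on a real trunk", {
  set.seed(63)
  cfg <- seqSubnetConfig("tiny", nFilters = 6L, denseSizes = c(6L, 3L),
                         lstmUnits = 4L, windowWidth = 200L, poolWidth = 40L)
  model <- buildSequenceOnly(cfg, seed = 63L)
  x <- seqchrom:::codeToOneHot(matrix(sample(1:4, 200L, TRUE), 1, 200L))[1, , ]
  # the adaptive rule drives the residual to ~tol relative to the span at
  # any base m, so both grids meet the same bound (an absolute floor
  # covers near-flat random-init models where the span is tiny)
  for (m in c(64L, 256L)) {
    tr <- integratedGradients(model, x, m = m)
    span <- abs(tr@fx - tr@fBaseline)
    expect_lt(completenessResidual(tr), max(0.01 * span, 1e-4))
  }
  expect_error(integratedGradients(model, x, m = 1L), "m >= 2")
})

test_that("bimodal attribution uses the seqscore head scaled by betaS", {
  L <- 25L
  lin <- linearSeqModel(L, seed = 64L)
  bim <- methods::new("BimodalModel", seqTrunk = lin@trunk,
                      chrTrunk = list(layers = list(), config = list()),
                      beta = c(b0 = 0.2, bS = 2.5, bC = 0.3),
                      kTracks = 1L, config = list())
  set.seed(65)
  x <- seqchrom:::codeToOneHot(matrix(sample(1:4, L, TRUE), 1, L))[1, , ]
  trSeq <- integratedGradients(linearSeqModel(L, seed = 64L, w = 2.5, b = 0),
                               x, m = 8L)
  trBim <- integratedGradients(bim, x, m = 8L)
  expect_equal(trBim@perChannel, trSeq@perChannel, tolerance = 1e-10)
})

test_that("findHills locates, merges and truncates peaks as documented", {
  a <- rep(0, 100)
  a[30] <- 5; a[29] <- 3; a[31] <- 3      # tall hill at index 30 (1-based)
  a[70] <- 2; a[69] <- 1.5; a[71] <- 1.5  # second hill
  h <- findHills(a, flank = 10L, smooth = 1L)
  expect_equal(h$peak, c(29, 69))          # 0-based
  expect_equal(h$start, c(19, 59))
  expect_equal(h$end, c(39, 79))
  expect_false(any(h$truncated))
  # peaks closer than a hill width merge, keeping the taller
  b <- rep(0, 100)
  b[40] <- 5; b[39] <- 4; b[41] <- 4
  b[50] <- 3; b[49] <- 2; b[51] <- 2
  h2 <- findHills(b, flank = 10L, smooth = 1L)
  expect_equal(h2$peak, 39)
  # a peak at the window edge is truncated
  d <- rep(0, 100); d[3] <- 5; d[2] <- 4; d[4] <- 4
  h3 <- findHills(d, flank = 10L, smooth = 1L)
  expect_true(h3$truncated[1])
  expect_equal(h3$start[1], 0)
  # negative attribution is ignored; flat signal yields no hills
  expect_equal(nrow(findHills(rep(-1, 50), smooth = 1L)), 0L)
})

test_that("findHills extracts the hill subsequences", {
  a <- rep(0, 60); a[30] <- 5; a[29] <- 3; a[31] <- 3
  s <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")
  h <- findHills(a, seq = s, flank = 3L, smooth = 1L)
  expect_equal(h$seq[1], substring(s, h$start[1] + 1L, h$end[1]))
  expect_equal(nchar(h$seq[1]), 6L)
})

test_that("countIupacKmer counts strand-unioned match starts", {
  expect_equal(countIupacKmer("CAGCTGCAGGTG"), 2L)
  # palindromic instance counted once despite matching both strands
  expect_equal(countIupacKmer("AACAGCTGAA", "CAGCTG"), 1L)
  # reverse-complement instance found on the + strand scan
  expect_equal(countIupacKmer("AACACCTGAA"), 1L)   # CACCTG = rc(CAGGTG)
  expect_equal(countIupacKmer("AAAAAAAAAA"), 0L)
  expect_equal(countIupacKmer(c("CAGCTG", "TTTTTT")), c(1L, 0L))
  expect_error(countIupacKmer("ACGT", "CAGX"), "IUPAC")
})

test_that("mean background k-mer count matches the analytic expectation", {
  set.seed(66)
  codes <- seqchrom:::sampleCodes(3000L, 200L, gcFraction = 0.5)
  seqs <- apply(codes, 1, function(r)
    paste(seqchrom:::codeToBase[r + 1L], collapse = ""))
  counts <- countIupacKmer(seqs, "CAGSTG")
  # per start: P(CAGSTG) = P(CASCTG) = 1/2048; overlap (CAGCTG) = 1/4096
  pStart <- 3 / 4096
  expected <- (200 - 6 + 1) * pStart
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 5 * se + 1e-3)
})

test_that("clusterHills separates two planted motif families", {
  set.seed(67)
  mkHill <- function(motif) {
    bg <- sample(c("A", "C", "G", "T"), 20, TRUE)
    at <- sample(1:14, 1)
    bg[at:(at + 5)] <- strsplit(motif, "")[[1]]
    paste(bg, collapse = "")
  }
  seqs <- c(replicate(40, mkHill("CAGCTG")), replicate(40, mkHill("GGGCGG")))
  truth <- rep(1:2, each = 40)
  res <- clusterHills(seqs, K = 2L, seed = 68L)
  expect_gte(adjustedRandIndex(res$cluster, truth), 0.9)
  expect_equal(sum(res$sizes), 80L)
  # determinism under the seed
  res2 <- clusterHills(seqs, K = 2L, seed = 68L)
  expect_identical(res$cluster, res2$cluster)
  expect_error(clusterHills(seqs[1:3], K = 5L), "at least K")
})

test_that("canonical k-mers collapse reverse complements", {
  cn <- seqchrom:::canonicalKmers(c("AAAAA", "TTTTT", "ACGTA", "TACGT"))
  expect_equal(cn[1], cn[2])
  expect_equal(cn[3], cn[4])
})

test_that("motifMultiplicityScan emits n scores per count, reproducibly", {
  model <- linearSeqModel(60L, seed = 69L)
  res <- motifMultiplicityScan(model, counts = 0:2, n = 20L, length = 60L,
                               seed = 70L)
  expect_equal(nrow(res), 60L)
  expect_equal(sort(unique(res$count)), 0:2)
  res2 <- motifMultiplicityScan(model, counts = 0:2, n = 20L, length = 60L,
                                seed = 70L)
  expect_identical(res, res2)
  expect_error(motifMultiplicityScan(model, counts = 1:20, n = 2L,
                                     length = 60L), "cannot fit")
})

test_that("flankScan scores the background row first and all variants", {
  model <- linearSeqModel(40L, seed = 71L)
  res <- flankScan(model, core = "CAGSTG", flankLen = 1L)
  # 4 left x 2 core resolutions x 4 right = 32 variants + background
  expect_equal(nrow(res), 33L)
  expect_equal(res$variant[1], "background")
  expect_true(all(c("CAGCTG", "CAGGTG") %in% res$core))
  expect_error(flankScan(model, flankLen = 4L), "cap")
})

test_that("attributeWindows defaults to bound windows", {
  sp <- quickSplit()
  model <- trainedModel(quickSeqRun())
  boundIdx <- which(bindingLabels(sp$test) == "bound")
  idx <- head(boundIdx, 2)
  out <- attributeWindows(model, sp$test, idx = idx, m = 8L)
  expect_length(out, 2L)
  expect_equal(names(out), as.character(idx))
  expect_s4_class(out[[1]], "AttributionTrack")
  expect_length(out[[1]]@perPosition, 500L)
})
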