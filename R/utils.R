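# internal helpers

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# small integer sub-seed derived from a master seed, kept below 2^31;
# arithmetic in doubles (exact below 2^53) to avoid integer overflow
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 97003 * as.numeric(offset)) %% 2147483587)
}

# nearest-rank sample quantile (type 1)
nearestRankQuantile <- function(x, q) {
  stats::quantile(x, probs = q, type = 1, names = FALSE)
}

# indices of the k largest (decreasing = TRUE) or smallest values of x,
# ties broken by original (genomic) order
topKByOrder <- function(x, k, decreasing = TRUE) {
  if (k <= 0) return(integer(0))
  ord <- order(if (decreasing) -x else x, seq_along(x))
  ord[seq_len(min(k, length(x)))]
}

codeToBase <- c("N", "A", "C", "G", "T")

# DNA string(s) -> integer code matrix (0=N, 1=A, 2=C, 3=G, 4=T)
seqToCode <- function(seqs) {
  seqs <- as.character(seqs)
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  n <- length(seqs)
  if (n == 0) return(matrix(0L, 0, 0))
  w <- nchar(seqs[1])
  out <- matrix(0L, n, w)
  for (i in seq_len(n)) out[i, ] <- lut[utf8ToInt(seqs[i])]
  out
}

# integer code matrix -> one-hot array (n, width, 4); N rows stay all-zero
codeToOneHot <- function(codes) {
  n <- nrow(codes); w <- ncol(codes)
  arr <- array(0, c(n, w, 4))
  hit <- which(codes > 0L)
  if (length(hit)) {
    rows <- ((hit - 1L) %% n) + 1L
    cols <- ((hit - 1L) %/% n) + 1L
    arr[cbind(rows, cols, codes[hit])] <- 1
  }
  arr
}

# timestamp = FALSE keeps the file byte-identical under a fixed seed
writeManifest <- function(path, fields, timestamp = TRUE) {
  fields$package <- as.character(utils::packageVersion("seqchrom"))
  if (timestamp) fields$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
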