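# Plain-text container for datasets and model checkpoints. The dataset
# container is a directory holding a window index TSV, the integer sequence
# codes, the flattened chromatin tensor, and a JSON manifest with the array
# schema; checkpoints pair an RDS weights file with a sidecar JSON recording
# the architecture, channel order, k, normalization target and seed so that
# embeddings are reproducible from the pair.

#' Serialize a ChromDataset to a directory
#'
#' @param dataset A \linkS4class{ChromDataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeChromDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gr <- windowRanges(dataset)
  idx <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    label = as.character(bindingLabels(dataset)),
                    accessible = accessibility(dataset))
  utils::write.table(idx, file.path(dir, "windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset@seqCode, file.path(dir, "seq_codes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  feat <- dataset@chromFeat
  dim(feat) <- c(dim(feat)[1], dim(feat)[2] * dim(feat)[3])
  utils::write.table(signif(feat, 8), file.path(dir, "chrom_feats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeManifest(file.path(dir, "dataset.json"),
                list(nWindows = nWindows(dataset),
                     width = ncol(dataset@seqCode),
                     nBins = dim(dataset@chromFeat)[2],
                     trackNames = dataset@trackNames,
                     normTotal = dataset@normTotal,
                     channelOrder = c("A", "C", "G", "T")),
                timestamp = FALSE)
  invisible(dir)
}

#' Read a serialized ChromDataset
#'
#' @param dir Directory written by \code{\link{writeChromDataset}}.
#' @return A \linkS4class{ChromDataset}.
#' @export
readChromDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "dataset.json"),
                             simplifyVector = TRUE)
  idx <- utils::read.table(file.path(dir, "windows.tsv"), header = TRUE,
                           sep = "\t")
  codes <- as.matrix(utils::read.table(file.path(dir, "seq_codes.tsv"),
                                       sep = "\t"))
  dimnames(codes) <- NULL
  storage.mode(codes) <- "integer"
  feat <- as.matrix(utils::read.table(file.path(dir, "chrom_feats.tsv"),
                                      sep = "\t"))
  dimnames(feat) <- NULL
  k <- length(man$trackNames)
  dim(feat) <- c(nrow(feat), man$nBins, k)
  methods::new("ChromDataset",
               rowRanges = GenomicRanges::GRanges(
                 idx$chrom, IRanges::IRanges(start = idx$start + 1L,
                                             end = idx$end)),
               seqCode = codes, chromFeat = feat,
               label = factor(idx$label,
                              levels = c("unbound", "bound", "ambiguous")),
               accessible = as.logical(idx$accessible),
               trackNames = man$trackNames, normTotal = man$normTotal)
}

#' Save a trained model checkpoint
#'
#' Writes the weights (RDS) plus a sidecar JSON describing architecture,
#' channel order, track count, and the training seed/mode if supplied.
#'
#' @param model A \linkS4class{SequenceModel} or \linkS4class{BimodalModel}.
#' @param path Checkpoint path (".rds" appended if missing); the sidecar is
#'   \code{<path>.json}.
#' @param extra Named list merged into the sidecar.
#' @return Invisibly, \code{path}.
#' @export
saveModel <- function(model, path, extra = list()) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(model, path)
  info <- list(class = class(model)[1],
               channelOrder = c("A", "C", "G", "T"),
               config = if (methods::is(model, "BimodalModel"))
                 model@config else model@config)
  if (methods::is(model, "BimodalModel")) {
    info$kTracks <- model@kTracks
    info$beta <- as.list(model@beta)
  }
  writeManifest(paste0(path, ".json"), c(info, extra))
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  readRDS(path)
}
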