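# 10x-style on-disk layout: matrix.mtx + features.tsv + barcodes.tsv, plus a
# cells.tsv carrying the per-cell sample/clone label. Matrix Market I/O goes
# through the Matrix package.

#' Write a count matrix as a 10x-style directory
#'
#' Emits `matrix.mtx` (Matrix Market sparse coordinate format),
#' `features.tsv` (id, name, type), `barcodes.tsv`, and `cells.tsv`
#' (barcode, sample label). Round-trips losslessly with [read_tenx()].
#'
#' @param m a [count_matrix()].
#' @param directory output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_tenx <- function(m, directory) {
  stopifnot(inherits(m, "CountMatrix"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create directory: ", directory)
  }
  Matrix::writeMM(m$counts, file.path(directory, "matrix.mtx"))
  utils::write.table(
    data.frame(id = m$gene_ids, name = m$gene_ids, type = "Gene Expression"),
    file.path(directory, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(m$barcodes, file.path(directory, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = m$barcodes, sample = m$sample_of_cell),
    file.path(directory, "cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(directory)
}

#' Read a 10x-style directory into a count matrix
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv`; a `cells.tsv`
#' with columns barcode/sample is used for per-cell sample labels when
#' present (all cells are labelled `"sample1"` otherwise). Mitochondrial
#' genes are flagged by name prefix.
#'
#' @param directory input directory.
#' @param mito_prefix gene-name prefix flagging mitochondrial genes
#'   (default `"mt-"`, mouse convention).
#' @return A [count_matrix()].
#' @export
read_tenx <- function(directory, mito_prefix = "mt-") {
  for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
    if (!file.exists(file.path(directory, f))) {
      stop("missing required file: ", file.path(directory, f))
    }
  }
  mm <- tryCatch(
    Matrix::readMM(file.path(directory, "matrix.mtx")),
    error = function(e) stop("malformed matrix.mtx in ", directory, ": ",
                             conditionMessage(e)))
  features <- tryCatch(
    utils::read.delim(file.path(directory, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed features.tsv in ", directory, ": ",
                             conditionMessage(e)))
  barcodes <- readLines(file.path(directory, "barcodes.tsv"))
  gene_ids <- as.character(features[[1]])
  if (length(gene_ids) != nrow(mm)) {
    stop("features.tsv lists ", length(gene_ids), " genes but matrix.mtx has ",
         nrow(mm), " rows")
  }
  if (length(barcodes) != ncol(mm)) {
    stop("barcodes.tsv lists ", length(barcodes), " cells but matrix.mtx has ",
         ncol(mm), " columns")
  }
  sample_of_cell <- rep("sample1", length(barcodes))
  cells_path <- file.path(directory, "cells.tsv")
  if (file.exists(cells_path)) {
    cells <- utils::read.delim(cells_path, header = TRUE,
                               stringsAsFactors = FALSE)
    idx <- match(barcodes, cells$barcode)
    if (anyNA(idx)) stop("cells.tsv does not cover all barcodes")
    sample_of_cell <- as.character(cells$sample[idx])
  }
  count_matrix(mm, gene_ids = gene_ids, barcodes = barcodes,
               sample_of_cell = if (length(barcodes)) sample_of_cell else character(0),
               mito_prefix = mito_prefix)
}
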