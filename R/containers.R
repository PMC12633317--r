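#' Construct a gene-by-cell count matrix container
#'
#' Bundles a sparse genes x cells matrix of non-negative integer counts with
#' gene identifiers, cell barcodes, a per-cell sample label and a per-gene
#' mitochondrial flag. This is the unit of exchange between the simulator,
#' the 10x-style reader/writer and the QC/normalization steps.
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param barcodes character vector of unique cell barcodes; defaults to
#'   `colnames(counts)`.
#' @param sample_of_cell per-cell sample (or clone) label; recycled from a
#'   single value, default `"sample1"`.
#' @param mito_flag logical per-gene flag marking mitochondrial genes;
#'   default: gene id starts with `mito_prefix`.
#' @param mito_prefix gene-name prefix used to derive `mito_flag` when it is
#'   not given (default `"mt-"`, the mouse convention).
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (dgCMatrix), `gene_ids`, `barcodes`, `sample_of_cell`, `mito_flag`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         barcodes = colnames(counts),
                         sample_of_cell = "sample1",
                         mito_flag = NULL, mito_prefix = "mt-") {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (inherits(counts, "nMatrix") || inherits(counts, "lMatrix")) {
    counts <- counts * 1  # pattern/logical MTX to numeric
  }
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids)) stop("gene_ids are required (or set rownames)")
  if (is.null(barcodes)) {
    barcodes <- if (ncol(counts) > 0) sprintf("cell%05d", seq_len(ncol(counts))) else character(0)
  }
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != nrow(counts)) {
    stop("gene_ids length (", length(gene_ids), ") != nrow(counts) (", nrow(counts), ")")
  }
  if (length(barcodes) != ncol(counts)) {
    stop("barcodes length (", length(barcodes), ") != ncol(counts) (", ncol(counts), ")")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("counts must be non-negative integers")
  }
  if (length(sample_of_cell) == 1) {
    sample_of_cell <- rep(sample_of_cell, ncol(counts))
  }
  if (length(sample_of_cell) != ncol(counts)) {
    stop("sample_of_cell must have one label per cell")
  }
  if (is.null(mito_flag)) mito_flag <- startsWith(gene_ids, mito_prefix)
  if (length(mito_flag) != length(gene_ids)) {
    stop("mito_flag must have one entry per gene")
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
                 sample_of_cell = as.character(sample_of_cell),
                 mito_flag = as.logical(mito_flag)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("<CountMatrix> %d genes x %d cells, %d samples, %d mito genes\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_of_cell)), sum(x$mito_flag)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Construct a normalized expression matrix container
#'
#' @param values genes x units matrix of finite real expression values
#'   (log scale for the `lognorm-per-cell` and `log2-pseudobulk` kinds).
#' @param norm_kind one of `"lognorm-per-cell"`, `"log2-pseudobulk"`,
#'   `"zscaled"`.
#' @param gene_ids,unit_ids identifiers; default taken from dimnames.
#' @param sample_of_cell optional per-unit sample label (carried along from
#'   the originating [count_matrix()] so downstream grouping operations can
#'   use it).
#' @return An object of class `NormalizedMatrix`.
#' @export
normalized_matrix <- function(values, norm_kind, gene_ids = rownames(values),
                              unit_ids = colnames(values),
                              sample_of_cell = NULL) {
  norm_kind <- match.arg(norm_kind,
                         c("lognorm-per-cell", "log2-pseudobulk", "zscaled"))
  if (is.null(gene_ids) || is.null(unit_ids)) {
    stop("values must carry gene and unit identifiers")
  }
  chk <- if (inherits(values, "sparseMatrix")) values@x else values
  if (length(chk) && any(!is.finite(chk))) stop("values must be finite")
  dimnames(values) <- list(gene_ids, unit_ids)
  if (!is.null(sample_of_cell) && length(sample_of_cell) != ncol(values)) {
    stop("sample_of_cell must have one label per unit")
  }
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 unit_ids = as.character(unit_ids), norm_kind = norm_kind,
                 sample_of_cell = sample_of_cell),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("<NormalizedMatrix [%s]> %d genes x %d units\n",
              x$norm_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)
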