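# QC, normalization, pseudobulk aggregation, gene-wise scaling and
# variable-gene selection.

#' QC thresholds with the two named presets
#'
#' Retention requires, with strict inequalities throughout:
#' total UMI `>` `min_umi`, detected features `>` `min_features`,
#' mitochondrial fraction `<` `max_mito_fraction`, and complexity
#' `log10(n_features)/log10(n_umi)` `>` `min_complexity`. The `"cd45"`
#' preset (immune-enriched samples) uses a UMI threshold of 200; the
#' `"total"` preset (whole tumor mixtures) uses the stricter threshold of
#' 500. Both share `min_features = 200`, `max_mito_fraction = 0.2`,
#' `min_complexity = 0.8`.
#'
#' @param preset `"cd45"` or `"total"`.
#' @param min_umi,min_features,max_mito_fraction,min_complexity overrides of
#'   individual thresholds.
#' @return An object of class `QCParams`.
#' @export
qc_params <- function(preset = c("cd45", "total"), min_umi = NULL,
                      min_features = 200, max_mito_fraction = 0.2,
                      min_complexity = 0.8) {
  preset <- match.arg(preset)
  min_umi <- min_umi %||% switch(preset, cd45 = 200, total = 500)
  if (min_umi < 0 || min_features < 0) stop("count thresholds must be >= 0")
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop("max_mito_fraction must be in [0,1]")
  }
  if (min_complexity < 0 || min_complexity > 1) {
    stop("min_complexity must be in [0,1]")
  }
  structure(list(preset = preset, min_umi = min_umi,
                 min_features = min_features,
                 max_mito_fraction = max_mito_fraction,
                 min_complexity = min_complexity),
            class = "QCParams")
}

#' Per-cell QC metrics
#'
#' @param m a [count_matrix()].
#' @return data.frame with one row per cell: `barcode`, `n_umi` (column
#'   sum), `n_features` (genes with nonzero count), `mito_fraction`
#'   (mitochondrial counts / total counts, 0 for empty cells), `complexity`
#'   (`log10(n_features)/log10(n_umi)`, defined as 0 when `n_umi <= 1`).
#' @export
compute_cell_qc_metrics <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  if (nrow(m$counts) == 0) stop("count matrix has no genes")
  n_umi <- Matrix::colSums(m$counts)
  n_features <- Matrix::colSums(m$counts > 0)
  mito <- Matrix::colSums(m$counts[m$mito_flag, , drop = FALSE])
  mito_fraction <- ifelse(n_umi > 0, mito / n_umi, 0)
  complexity <- ifelse(n_umi > 1, log10(pmax(n_features, 1)) / log10(n_umi), 0)
  data.frame(barcode = m$barcodes, n_umi = as.numeric(n_umi),
             n_features = as.numeric(n_features),
             mito_fraction = as.numeric(mito_fraction),
             complexity = as.numeric(complexity),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter cells on the four QC rules
#'
#' A cell is retained iff all four strict inequalities of [qc_params()]
#' hold. The report counts removals by the first failing rule (in the order
#' UMI, features, mito, complexity) plus the total.
#'
#' @param m a [count_matrix()].
#' @param p a [qc_params()] object.
#' @return List with `matrix` (filtered [count_matrix()]), `metrics`
#'   (per-cell metrics with a `retained` flag), and `report` (removals per
#'   rule).
#' @export
qc_filter <- function(m, p) {
  stopifnot(inherits(m, "CountMatrix"), inherits(p, "QCParams"))
  met <- compute_cell_qc_metrics(m)
  pass_umi <- met$n_umi > p$min_umi
  pass_feat <- met$n_features > p$min_features
  pass_mito <- met$mito_fraction < p$max_mito_fraction
  pass_cplx <- met$complexity > p$min_complexity
  keep <- pass_umi & pass_feat & pass_mito & pass_cplx
  first_fail <- rep(NA_character_, nrow(met))
  first_fail[!pass_cplx] <- "complexity"
  first_fail[!pass_mito] <- "mito_fraction"
  first_fail[!pass_feat] <- "n_features"
  first_fail[!pass_umi] <- "n_umi"
  report <- data.frame(
    rule = c("n_umi", "n_features", "mito_fraction", "complexity", "total"),
    removed = c(sum(first_fail == "n_umi", na.rm = TRUE),
                sum(first_fail == "n_features", na.rm = TRUE),
                sum(first_fail == "mito_fraction", na.rm = TRUE),
                sum(first_fail == "complexity", na.rm = TRUE),
                sum(!keep)),
    stringsAsFactors = FALSE)
  if (!any(keep)) warning("QC filtering removed every cell")
  met$retained <- keep
  filtered <- count_matrix(m$counts[, keep, drop = FALSE],
                           gene_ids = m$gene_ids,
                           barcodes = m$barcodes[keep],
                           sample_of_cell = m$sample_of_cell[keep],
                           mito_flag = m$mito_flag)
  list(matrix = filtered, metrics = met, report = report)
}

#' Per-cell log normalization
#'
#' `value(g, c) = ln(1 + scale * count(g, c) / total(c))`, the usual
#' library-size normalization followed by natural-log log1p.
#'
#' @param m a [count_matrix()]; every cell must have a positive total.
#' @param scale scale factor (default 1e4).
#' @return A [normalized_matrix()] of kind `"lognorm-per-cell"` (sparse),
#'   carrying the per-cell sample labels.
#' @export
lognormalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "CountMatrix"), scale > 0)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    stop("cells with zero total counts present (",
         sum(totals == 0), "); run QC filtering first")
  }
  v <- m$counts
  v@x <- log1p(scale * v@x / rep.int(totals, diff(v@p)))
  normalized_matrix(v, "lognorm-per-cell", gene_ids = m$gene_ids,
                    unit_ids = m$barcodes, sample_of_cell = m$sample_of_cell)
}

#' Pseudobulk aggregation by sample
#'
#' Sums raw counts over all cells of each group; groups appear in order of
#' first appearance among the cells.
#'
#' On request the sums are log2-transformed for cross-dataset use: by
#' default they are first library-size normalized to counts per million
#' (`log2(1 + 1e6 * sum(g,s) / total(s))`), which removes the arbitrary
#' per-sample offset that raw cell numbers would otherwise contribute and
#' puts pseudobulk profiles on the same per-library scale as a bulk
#' (TPM-like) reference panel; set `scale = NULL` for plain
#' `log2(1 + sum)`.
#'
#' @param m a [count_matrix()].
#' @param groupby `"sample"` (uses `m$sample_of_cell`) or a per-cell label
#'   vector of length `ncol(m)`.
#' @param log2 if `TRUE`, return a [normalized_matrix()] of kind
#'   `"log2-pseudobulk"`; otherwise the raw genes x groups matrix of summed
#'   counts.
#' @param scale library-size scale factor of the log2 transform (default
#'   1e6, i.e. counts per million); `NULL` disables library-size
#'   normalization.
#' @return Matrix of summed counts, or a [normalized_matrix()] when
#'   `log2 = TRUE`.
#' @export
pseudobulk <- function(m, groupby = "sample", log2 = FALSE, scale = 1e6) {
  stopifnot(inherits(m, "CountMatrix"))
  if (is.character(groupby) && length(groupby) == 1) {
    if (!identical(groupby, "sample")) {
      stop("unknown label key: ", groupby, " (use \"sample\" or a label vector)")
    }
    labels <- m$sample_of_cell
  } else {
    labels <- as.character(groupby)
    if (length(labels) != ncol(m$counts)) {
      stop("groupby labels must have one entry per cell")
    }
  }
  groups <- unique(labels)
  sums <- vapply(groups, function(g) {
    Matrix::rowSums(m$counts[, labels == g, drop = FALSE])
  }, numeric(nrow(m$counts)))
  sums <- matrix(sums, nrow = nrow(m$counts),
                 dimnames = list(m$gene_ids, groups))
  if (!log2) return(sums)
  vals <- if (is.null(scale)) {
    base::log2(1 + sums)
  } else {
    totals <- colSums(sums)
    if (any(totals == 0)) stop("pseudobulk group with zero total counts")
    base::log2(1 + scale * sweep(sums, 2, totals, "/"))
  }
  normalized_matrix(vals, "log2-pseudobulk",
                    gene_ids = m$gene_ids, unit_ids = groups)
}

#' Gene-wise z-scaling
#'
#' Each gene row is standardized to mean 0 and sd 1 across units, using the
#' population (divide-by-n) sd convention; constant genes map to all-zero
#' rows.
#'
#' @param x a [normalized_matrix()] or plain genes x units matrix with at
#'   least two units.
#' @return A [normalized_matrix()] of kind `"zscaled"` (dense).
#' @export
zscale_genes <- function(x) {
  ex <- as_expr_matrix(x)
  if (ncol(ex$values) < 2) stop("z-scaling requires at least 2 units")
  normalized_matrix(row_zscale(ex$values), "zscaled",
                    gene_ids = rownames(ex$values),
                    unit_ids = colnames(ex$values),
                    sample_of_cell = ex$sample_of_cell)
}

#' Select variable genes by cross-group log2 spread
#'
#' A gene is selected iff its maximum minus minimum group mean on the log2
#' scale strictly exceeds the fold-change threshold.
#'
#' @param group_means genes x groups matrix of log2-scale group means
#'   (at least two groups).
#' @param log2fc_threshold positive threshold, default 1.5.
#' @return Character vector of selected gene ids.
#' @export
select_variable_genes <- function(group_means, log2fc_threshold = 1.5) {
  group_means <- as.matrix(group_means)
  if (ncol(group_means) < 2) {
    stop("variable-gene selection requires at least 2 groups")
  }
  if (log2fc_threshold <= 0) stop("log2fc_threshold must be > 0")
  spread <- apply(group_means, 1, max) - apply(group_means, 1, min)
  rownames(group_means)[spread > log2fc_threshold]
}
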