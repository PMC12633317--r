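# Marker-based annotation, composition tables, trend statistics, dot-plot
# summaries and gene-score correlation.

#' Annotate cells by marker-gene argmax
#'
#' Per cell, the subtype is the argmax over subtypes of the mean expression
#' of that subtype's marker genes, assigned only when the maximum exceeds
#' `floor`; otherwise the cell is `"unassigned"`. Markers absent from the
#' matrix are skipped with a warning.
#'
#' @param x a [normalized_matrix()] of per-cell expression (carrying sample
#'   labels), or a genes x cells matrix plus `samples`.
#' @param marker_map named list: subtype -> character vector of marker
#'   genes.
#' @param floor assignment floor on the best mean marker expression
#'   (default 0).
#' @param samples optional per-cell sample labels overriding the ones
#'   carried by `x`.
#' @return data.frame of class `CellAnnotation`: `barcode`, `subtype`,
#'   `sample`.
#' @export
annotate_by_markers <- function(x, marker_map, floor = 0, samples = NULL) {
  if (!length(marker_map) || is.null(names(marker_map))) {
    stop("marker_map must be a non-empty named list")
  }
  ex <- as_expr_matrix(x)
  v <- ex$values
  samples <- samples %||% ex$sample_of_cell %||% rep("sample1", ncol(v))
  if (length(samples) != ncol(v)) stop("samples must have one label per cell")
  means <- vapply(names(marker_map), function(st) {
    present <- intersect(marker_map[[st]], rownames(v))
    missing <- setdiff(marker_map[[st]], present)
    if (length(missing)) {
      warning("subtype ", st, ": marker(s) absent and skipped: ",
              paste(missing, collapse = ", "))
    }
    if (!length(present)) return(rep(-Inf, ncol(v)))
    colMeans(v[present, , drop = FALSE])
  }, numeric(ncol(v)))
  means <- matrix(means, ncol = length(marker_map),
                  dimnames = list(colnames(v), names(marker_map)))
  best <- max.col(means, ties.method = "first")
  best_val <- means[cbind(seq_len(nrow(means)), best)]
  subtype <- ifelse(best_val > floor, names(marker_map)[best], "unassigned")
  out <- data.frame(barcode = colnames(v), subtype = subtype,
                    sample = as.character(samples),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("CellAnnotation", "data.frame")
  out
}

#' Sample-by-subtype composition table
#'
#' Proportions are over assigned cells only (`"unassigned"` cells are
#' excluded from the denominator and reported separately); each row sums to
#' one. Samples with zero assigned cells are dropped with a warning. When
#' `emt_rank` is given, rows are ordered by it (0 = most epithelial).
#'
#' @param a a [annotate_by_markers()] result (or a data.frame with columns
#'   `sample` and `subtype`).
#' @param emt_rank optional named integer vector: sample -> rank along the
#'   EMT spectrum.
#' @return An object of class `CompositionTable`: list with `proportions`
#'   (samples x subtypes), `n_cells`, `n_unassigned`, `emt_rank`.
#' @export
composition_table <- function(a, emt_rank = NULL) {
  stopifnot(all(c("sample", "subtype") %in% names(a)))
  assigned <- a[a$subtype != "unassigned", , drop = FALSE]
  n_unassigned <- table(factor(a$sample[a$subtype == "unassigned"],
                               levels = unique(a$sample)))
  empty <- setdiff(unique(a$sample), unique(assigned$sample))
  if (length(empty)) {
    warning("sample(s) with zero assigned cells excluded: ",
            paste(empty, collapse = ", "))
  }
  tab <- table(assigned$sample, assigned$subtype)
  props <- sweep(unclass(tab), 1, rowSums(tab), "/")
  samples <- rownames(props)
  if (!is.null(emt_rank)) {
    if (!all(samples %in% names(emt_rank))) {
      stop("emt_rank must name every sample with assigned cells")
    }
    ord <- order(emt_rank[samples])
    props <- props[ord, , drop = FALSE]
    samples <- rownames(props)
  }
  structure(list(proportions = props,
                 n_cells = as.integer(rowSums(tab)[samples]),
                 n_unassigned = as.integer(n_unassigned[samples]),
                 emt_rank = if (is.null(emt_rank)) NULL else emt_rank[samples]),
            class = "CompositionTable")
}

#' @export
print.CompositionTable <- function(x, ...) {
  cat(sprintf("<CompositionTable> %d samples x %d subtypes\n",
              nrow(x$proportions), ncol(x$proportions)))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Linear trend test along the ordered EMT spectrum
#'
#' Ordinary least-squares regression of a per-sample statistic on its
#' integer EMT rank, with the usual two-sided t-test on the slope.
#'
#' @param values per-sample statistic.
#' @param ranks distinct EMT ranks (same length, at least 3 samples).
#' @return List of class `TrendResult`: `slope`, `intercept`, `p_value`,
#'   `n`.
#' @export
trend_test <- function(values, ranks) {
  if (length(values) != length(ranks)) stop("values and ranks must align")
  if (length(values) < 3) stop("trend test requires at least 3 samples")
  if (anyDuplicated(ranks)) stop("ranks must be distinct")
  fit <- stats::lm(values ~ ranks)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm["ranks", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 p_value = unname(sm["ranks", "Pr(>|t|)"]),
                 n = length(values)),
            class = "TrendResult")
}

#' @export
print.TrendResult <- function(x, ...) {
  cat(sprintf("<TrendResult> slope %.4g, p = %.3g (n = %d)\n",
              x$slope, x$p_value, x$n))
  invisible(x)
}

#' Dot-plot statistics per gene and group
#'
#' For every (gene, group): the fraction of the group's cells with
#' expression > 0, and the mean expression over all of the group's cells
#' (zeros included). Missing genes are skipped with a warning; empty groups
#' cannot arise from a label vector.
#'
#' @param x a [normalized_matrix()] of per-cell expression.
#' @param genes genes to summarize.
#' @param groupby per-cell group labels, or `NULL` to use the sample labels
#'   carried by `x`.
#' @return data.frame with columns `gene`, `group`, `frac_expressing`,
#'   `mean_expr`.
#' @export
dotplot_stats <- function(x, genes, groupby = NULL) {
  ex <- as_expr_matrix(x)
  v <- ex$values
  groupby <- groupby %||% ex$sample_of_cell
  if (is.null(groupby) || length(groupby) != ncol(v)) {
    stop("groupby must give one label per cell")
  }
  present <- intersect(genes, rownames(v))
  missing <- setdiff(genes, present)
  if (length(missing)) {
    warning("gene(s) absent and skipped: ", paste(missing, collapse = ", "))
  }
  if (!length(present)) stop("none of the requested genes are present")
  groups <- unique(groupby)
  out <- expand.grid(gene = present, group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$frac_expressing <- NA_real_
  out$mean_expr <- NA_real_
  for (g in groups) {
    sub <- v[present, groupby == g, drop = FALSE]
    idx <- out$group == g
    out$frac_expressing[idx] <- rowMeans(sub > 0)
    out$mean_expr[idx] <- rowMeans(sub)
  }
  out
}

#' Pearson correlation between one gene and an EMT score
#'
#' @param x a [normalized_matrix()] (cells or pseudobulk samples).
#' @param gene gene identifier present in `x`.
#' @param scores named numeric score vector (names matched against the
#'   units of `x`), e.g. a harmonized column of an [emt_score_table()].
#' @return List with `r`, `p_value`, `n`.
#' @export
gene_score_correlation <- function(x, gene, scores) {
  ex <- as_expr_matrix(x)
  v <- ex$values
  if (!gene %in% rownames(v)) stop("gene not present: ", gene)
  units <- intersect(colnames(v), names(scores))
  if (length(units) < 3) stop("correlation requires at least 3 shared units")
  gx <- v[gene, units]
  sx <- scores[units]
  if (stats::sd(gx) == 0) stop("correlation undefined: gene ", gene, " is constant")
  if (stats::sd(sx) == 0) stop("correlation undefined: scores are constant")
  ct <- stats::cor.test(gx, sx, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(units))
}
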