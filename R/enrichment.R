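# Rank-based gene-set enrichment: per sample, in-set gene means are
# compared against all out-of-set gene means with a Wilcoxon-Mann-Whitney
# statistic under the tie-corrected normal approximation, yielding one
# z-score per (gene set, sample) - the shape of a pathway-by-sample
# enrichment heatmap.

#' Load gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are de-duplicated with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of class `GeneSetCollection`,
#'   with per-set descriptions in `attr(, "description")`.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields, got ", length(fields))
    }
    name <- fields[1]
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("set ", name, ": duplicate gene(s) de-duplicated")
      genes <- unique(genes)
    }
    if (name %in% names(sets)) stop("duplicate set name: ", name)
    sets[[name]] <- genes
    descs[name] <- fields[2]
  }
  structure(sets, description = descs, class = "GeneSetCollection")
}

# Tie-corrected normal-approximation z for a Mann-Whitney U comparing
# in-set values against out-of-set values, with continuity correction.
wmw_z <- function(in_values, out_values, continuity = TRUE) {
  n1 <- length(in_values)
  n2 <- length(out_values)
  n <- n1 + n2
  r <- rank(c(in_values, out_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("all values tied; degenerate WMW statistic, z set to 0")
    return(0)
  }
  d <- u - mu
  cc <- if (continuity) 0.5 * sign(d) else 0
  (d - cc) / sqrt(sigma2)
}

#' Wilcoxon-Mann-Whitney gene-set enrichment z-scores
#'
#' Per group, each gene's expression is summarized as its mean over the
#' group's cells; per (set, group), the in-set gene means are compared with
#' all out-of-set gene means through the Mann-Whitney U statistic and
#' converted to a z-score with continuity correction and tie-corrected
#' variance under the normal approximation. Sets with fewer than 2 genes in
#' the matrix are skipped with a warning.
#'
#' @param x a [normalized_matrix()] of per-cell expression.
#' @param sets a [load_gmt()] collection (or named list of gene vectors).
#' @param groupby per-cell group labels, or `NULL` to use the sample labels
#'   carried by `x`.
#' @return An object of class `EnrichmentResult`: a sets x groups matrix of
#'   z-scores with `attr(, "row_scaled") = FALSE`.
#' @export
wmw_enrichment_z <- function(x, sets, groupby = NULL) {
  ex <- as_expr_matrix(x)
  v <- ex$values
  groupby <- groupby %||% ex$sample_of_cell
  if (is.null(groupby) || length(groupby) != ncol(v)) {
    stop("groupby must give one label per cell")
  }
  groups <- unique(groupby)
  gene_means <- vapply(groups, function(g) {
    rowMeans(v[, groupby == g, drop = FALSE])
  }, numeric(nrow(v)))
  gene_means <- matrix(gene_means, nrow = nrow(v),
                       dimnames = list(rownames(v), groups))
  usable <- vapply(sets, function(gs) {
    length(intersect(gs, rownames(v))) >= 2
  }, logical(1))
  if (any(!usable)) {
    warning("set(s) with < 2 matrix genes skipped: ",
            paste(names(sets)[!usable], collapse = ", "))
  }
  sets <- sets[usable]
  if (!length(sets)) stop("no usable gene sets")
  z <- matrix(NA_real_, nrow = length(sets), ncol = length(groups),
              dimnames = list(names(sets), groups))
  for (s in names(sets)) {
    in_idx <- rownames(v) %in% sets[[s]]
    for (g in groups) {
      z[s, g] <- wmw_z(gene_means[in_idx, g], gene_means[!in_idx, g])
    }
  }
  structure(z, row_scaled = FALSE, class = c("EnrichmentResult", "matrix"))
}

#' Row-scale an enrichment matrix for display
#'
#' Standardizes each set's z-scores across groups (population sd), so the
#' heatmap shows relative enrichment per pathway; constant rows become
#' zeros.
#'
#' @param e an [wmw_enrichment_z()] result with at least 2 groups.
#' @return The row-scaled `EnrichmentResult`.
#' @export
zscale_rows <- function(e) {
  stopifnot(inherits(e, "EnrichmentResult"))
  if (ncol(e) < 2) stop("row scaling requires at least 2 groups")
  out <- row_zscale(unclass(e))
  structure(out, row_scaled = TRUE, class = c("EnrichmentResult", "matrix"))
}
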