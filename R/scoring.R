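# The three EMT scoring metrics and their harmonization.
#
# Sign conventions before harmonization:
#   * 76GS: anchor-correlation-weighted sum, mean-centered; higher = more
#     epithelial.
#   * KS: signed sup-distance between the epithelial and mesenchymal
#     signature expression distributions within one unit; in [-1, 1],
#     positive = mesenchymal.
#   * MLR: expected class 0*P(E) + 1*P(H) + 2*P(M) from a three-class
#     multinomial model; in [0, 2], 2 = mesenchymal.
# harmonize_scores() flips KS and MLR so that higher always means more
# epithelial, matching the 76GS scale.

#' 76-gene signature EMT score
#'
#' Each signature gene is weighted by its Pearson correlation with the
#' anchor gene across the scored units; a unit's score is the weighted sum
#' of its signature-gene expression, and scores are mean-centered across
#' units. Signature genes absent from the matrix are dropped with a
#' warning. Higher scores indicate a more epithelial phenotype.
#'
#' @param x a [normalized_matrix()] (or genes x units matrix) with at least
#'   3 units.
#' @param sig a [gene_signature()]; the anchor gene must be present and
#'   non-constant.
#' @param center mean-center the scores (default TRUE).
#' @return Named numeric vector of per-unit scores.
#' @export
score_76gs <- function(x, sig, center = TRUE) {
  stopifnot(inherits(sig, "GeneSignature"))
  v <- as_expr_matrix(x)$values
  if (ncol(v) < 3) stop("76GS scoring requires at least 3 units")
  if (!sig$anchor_gene %in% rownames(v)) {
    stop("anchor gene ", sig$anchor_gene, " absent from the matrix")
  }
  anchor <- v[sig$anchor_gene, ]
  if (stats::sd(anchor) == 0) {
    stop("anchor gene ", sig$anchor_gene,
         " is constant across units; weights are undefined")
  }
  present <- intersect(sig$gs76_genes, rownames(v))
  missing <- setdiff(sig$gs76_genes, present)
  if (length(missing)) {
    warning(length(missing), " signature gene(s) absent and dropped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }
  if (!length(present)) stop("no signature genes present in the matrix")
  sub <- v[present, , drop = FALSE]
  keep <- apply(sub, 1, stats::sd) > 0
  w <- numeric(nrow(sub))
  w[keep] <- as.vector(stats::cor(t(sub[keep, , drop = FALSE]), anchor))
  scores <- as.vector(w %*% sub)
  names(scores) <- colnames(v)
  if (center) scores <- scores - mean(scores)
  scores
}

# Signed KS statistic for one unit: epithelial vs mesenchymal signature
# expression ECDFs evaluated over the pooled value grid.
ks_signed <- function(epi_values, mes_values, warn_tie = TRUE) {
  grid <- sort(unique(c(epi_values, mes_values)))
  f_e <- stats::ecdf(epi_values)(grid)
  f_m <- stats::ecdf(mes_values)(grid)
  d_mes <- max(f_e - f_m)
  d_epi <- max(f_m - f_e)
  if (warn_tie && d_mes == d_epi && d_mes > 0) {
    message("KS tie (D_mes == D_epi == ", format(d_mes), "); resolved as +D_mes")
  }
  if (d_mes >= d_epi) d_mes else -d_epi
}

#' Kolmogorov-Smirnov EMT score
#'
#' Per unit, compares the empirical distribution of epithelial-signature
#' expression values F_E with that of mesenchymal-signature values F_M:
#' `D_mes = sup(F_E - F_M)`, `D_epi = sup(F_M - F_E)`, and the raw score is
#' `D_mes` if `D_mes >= D_epi`, else `-D_epi`. Bounded in `[-1, 1]`,
#' positive = mesenchymal. Used as a continuous score (no p-value gate).
#'
#' @inheritParams score_76gs
#' @param sig a [gene_signature()]; at least 2 epithelial and 2 mesenchymal
#'   genes must be present in the matrix.
#' @return Named numeric vector of raw per-unit scores in `[-1, 1]`.
#' @export
score_ks <- function(x, sig) {
  stopifnot(inherits(sig, "GeneSignature"))
  v <- as_expr_matrix(x)$values
  epi <- intersect(sig$epithelial_genes, rownames(v))
  mes <- intersect(sig$mesenchymal_genes, rownames(v))
  if (length(epi) < 2 || length(mes) < 2) {
    stop("KS score needs >= 2 genes per arm; missing epithelial: ",
         paste(utils::head(setdiff(sig$epithelial_genes, epi), 5), collapse = ", "),
         "; missing mesenchymal: ",
         paste(utils::head(setdiff(sig$mesenchymal_genes, mes), 5), collapse = ", "))
  }
  scores <- vapply(seq_len(ncol(v)), function(u) {
    ks_signed(v[epi, u], v[mes, u])
  }, numeric(1))
  stats::setNames(scores, colnames(v))
}

# Per-unit MLR predictors: mean z-scored expression of the epithelial and
# mesenchymal gene lists. Inputs already of kind "zscaled" are used as-is.
mlr_predictors <- function(x, sig) {
  ex <- as_expr_matrix(x)
  v <- if (identical(ex$kind, "zscaled")) ex$values else row_zscale(ex$values)
  rownames(v) <- rownames(ex$values)
  epi <- intersect(sig$epithelial_genes, rownames(v))
  mes <- intersect(sig$mesenchymal_genes, rownames(v))
  if (!length(epi) || !length(mes)) {
    stop("MLR predictors need at least one epithelial and one mesenchymal gene")
  }
  data.frame(epi = colMeans(v[epi, , drop = FALSE]),
             mes = colMeans(v[mes, , drop = FALSE]),
             row.names = colnames(ex$values))
}

#' Multinomial-regression EMT score
#'
#' Fits a three-class (E / H / M: epithelial, hybrid, mesenchymal)
#' multinomial logistic model by maximum likelihood on labelled training
#' units, using two predictors per unit: the mean z-scored expression of
#' the epithelial genes and of the mesenchymal genes. The raw score of a
#' unit is the expected class `0*P(E) + 1*P(H) + 2*P(M)`, bounded in
#' `[0, 2]` with 2 = mesenchymal. A small ridge penalty (`decay`)
#' regularizes the fit when classes are nearly separable.
#'
#' @inheritParams score_76gs
#' @param training a [normalized_matrix()] (or matrix) of training units.
#' @param training_classes factor/character of classes `E`, `H`, `M`, one
#'   per training unit; all three classes must be present.
#' @param decay ridge (weight-decay) penalty of the multinomial fit,
#'   default 1e-3.
#' @param maxit maximum fitting iterations.
#' @return Named numeric vector of raw scores in `[0, 2]`, with the class
#'   probability matrix in `attr(, "probabilities")` and the fitted
#'   coefficients in `attr(, "coefficients")`.
#' @export
score_mlr <- function(x, sig, training, training_classes, decay = 1e-3,
                      maxit = 500) {
  stopifnot(inherits(sig, "GeneSignature"))
  training_classes <- as.character(training_classes)
  missing_cls <- setdiff(c("E", "H", "M"), unique(training_classes))
  if (length(missing_cls)) {
    stop("training units must cover classes E, H and M; missing: ",
         paste(missing_cls, collapse = ", "))
  }
  train_df <- mlr_predictors(training, sig)
  train_df$class <- factor(training_classes, levels = c("E", "H", "M"))
  fit <- nnet::multinom(class ~ epi + mes, data = train_df, trace = FALSE,
                        decay = decay, maxit = maxit)
  if (!is.null(fit$convergence) && fit$convergence != 0) {
    stop("multinomial fit did not converge within ", maxit,
         " iterations (final deviance ", format(fit$deviance), ")")
  }
  newdata <- mlr_predictors(x, sig)
  probs <- stats::predict(fit, newdata = newdata, type = "probs")
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, names(probs)))
  scores <- probs[, "H"] + 2 * probs[, "M"]
  names(scores) <- rownames(newdata)
  rownames(probs) <- rownames(newdata)
  attr(scores, "probabilities") <- probs
  attr(scores, "coefficients") <- stats::coef(fit)
  scores
}

#' Label units E / H / M by EMT-parameter tertiles
#'
#' Convenience for training [score_mlr()] on a synthetic reference panel:
#' theta < 1/3 is epithelial (E), theta < 2/3 hybrid (H), the rest
#' mesenchymal (M).
#'
#' @param theta numeric vector in `[0, 1]`.
#' @return Character vector of classes.
#' @export
theta_classes <- function(theta) {
  ifelse(theta < 1 / 3, "E", ifelse(theta < 2 / 3, "H", "M"))
}

#' Assemble an EMT score table
#'
#' @param unit_ids unit identifiers.
#' @param score_76gs,score_ks_raw,score_mlr_raw per-unit scores on their
#'   native scales.
#' @return data.frame of class `EMTScoreTable`.
#' @export
emt_score_table <- function(unit_ids, score_76gs, score_ks_raw, score_mlr_raw) {
  df <- data.frame(unit_id = as.character(unit_ids),
                   score_76gs = as.numeric(score_76gs),
                   score_ks_raw = as.numeric(score_ks_raw),
                   score_mlr_raw = as.numeric(score_mlr_raw),
                   stringsAsFactors = FALSE)
  class(df) <- c("EMTScoreTable", "data.frame")
  df
}

#' Harmonize score directionality
#'
#' Flips KS and MLR onto the 76GS scale so that higher always means more
#' epithelial: `harmonized_76gs = score_76gs`, `harmonized_ks =
#' -score_ks_raw`, `harmonized_mlr = 2 - score_mlr_raw` (range-preserving
#' reflection of `[0, 2]`).
#'
#' @param t an [emt_score_table()].
#' @return The table with `harmonized_76gs`, `harmonized_ks`,
#'   `harmonized_mlr` columns added.
#' @export
harmonize_scores <- function(t) {
  stopifnot(inherits(t, "EMTScoreTable"))
  t$harmonized_76gs <- t$score_76gs
  t$harmonized_ks <- -t$score_ks_raw
  t$harmonized_mlr <- 2 - t$score_mlr_raw
  t
}

#' Concordance of the three harmonized scores
#'
#' @param t a harmonized [emt_score_table()] with at least 3 units.
#' @return 3x3 symmetric Pearson correlation matrix with unit diagonal.
#' @export
concordance_matrix <- function(t) {
  stopifnot(inherits(t, "EMTScoreTable"))
  cols <- c("harmonized_76gs", "harmonized_ks", "harmonized_mlr")
  if (!all(cols %in% names(t))) {
    stop("run harmonize_scores() first; harmonized columns missing")
  }
  if (nrow(t) < 3) stop("concordance requires at least 3 units")
  for (cl in cols) {
    if (stats::sd(t[[cl]]) == 0) {
      stop("correlation undefined: column ", cl, " is constant")
    }
  }
  stats::cor(as.matrix(t[, cols]))
}

#' Compute all three scores on one matrix
#'
#' @inheritParams score_mlr
#' @return A harmonized [emt_score_table()].
#' @export
emt_scores <- function(x, sig, training, training_classes, decay = 1e-3) {
  s76 <- score_76gs(x, sig)
  sks <- score_ks(x, sig)
  smlr <- score_mlr(x, sig, training, training_classes, decay = decay)
  harmonize_scores(emt_score_table(names(s76), s76, sks[names(s76)],
                                   smlr[names(s76)]))
}

#' Place pseudobulk queries onto a bulk reference panel
#'
#' Restricts the query log2 pseudobulk and the panel to their shared genes,
#' concatenates them, applies gene-wise z-scaling jointly across the
#' combined set, and computes all three harmonized scores on the combined
#' matrix (the MLR model is trained on the panel portion). Each query's
#' rank among the panel samples on the harmonized 76GS score is returned
#' (rank 1 = most mesenchymal).
#'
#' @param query a [normalized_matrix()] of kind `"log2-pseudobulk"` (or a
#'   genes x samples log2 matrix).
#' @param panel a `ReferencePanel` (unscaled log2 values).
#' @param sig a [gene_signature()].
#' @param panel_classes E/H/M training classes for the panel samples;
#'   derived from the panel's theta tertiles when `NULL`.
#' @param min_overlap minimum number of shared genes (default 50).
#' @return List with `scores` (harmonized [emt_score_table()] with an
#'   `is_query` column), `query_rank` (named integer vector), `combined`
#'   (the jointly scaled [normalized_matrix()]), and `n_shared_genes`.
#' @export
place_on_reference <- function(query, panel, sig, panel_classes = NULL,
                               min_overlap = 50) {
  stopifnot(inherits(panel, "ReferencePanel"))
  if (panel$scaled_flag) {
    stop("panel must be on the unscaled log2 scale; joint scaling is applied here")
  }
  qv <- as_expr_matrix(query)$values
  shared <- intersect(rownames(qv), panel$gene_ids)
  if (length(shared) < min_overlap) {
    stop("gene overlap between query and panel too small: ", length(shared),
         " < ", min_overlap)
  }
  pv <- t(panel$values[, shared, drop = FALSE])
  combined <- cbind(pv, qv[shared, , drop = FALSE])
  scaled <- zscale_genes(normalized_matrix(combined, "log2-pseudobulk"))
  if (is.null(panel_classes)) {
    if (is.null(panel$theta)) {
      stop("panel_classes required when the panel carries no theta labels")
    }
    panel_classes <- theta_classes(panel$theta)
  }
  n_panel <- ncol(pv)
  training <- normalized_matrix(scaled$values[, seq_len(n_panel), drop = FALSE],
                                "zscaled")
  tab <- emt_scores(scaled, sig, training, panel_classes)
  tab$is_query <- c(rep(FALSE, n_panel), rep(TRUE, ncol(qv)))
  panel_scores <- tab$harmonized_76gs[!tab$is_query]
  query_rank <- vapply(tab$harmonized_76gs[tab$is_query], function(s) {
    sum(panel_scores < s) + 1L
  }, integer(1))
  names(query_rank) <- tab$unit_id[tab$is_query]
  list(scores = tab, query_rank = query_rank, combined = scaled,
       n_shared_genes = length(shared))
}
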