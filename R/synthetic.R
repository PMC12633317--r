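# Synthetic tumor-microenvironment generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a set of clonal tumors ordered along an EMT parameter theta in
# [0,1] (0 = epithelial, 1 = mesenchymal), with
#   * epithelial-program genes (Cdh1/Epcam/claudin/MHC/Tacstd2 analogs)
#     whose negative-binomial means decline log-linearly in theta,
#   * mesenchymal-program genes (Vim/Snai1/Gpnmb/Mmp11 analogs) that rise,
#   * an immune compartment whose subtype mix shifts with theta (cytotoxic
#     CD8 and plasma cells down, Tregs and Cd25+Cd69+ regulatory-like B
#     cells up) and whose CD8/NK effector genes (Gzmb, Gzma, Prf1, Ccr5,
#     Cxcr6 analogs) decline with theta,
#   * a bulk reference panel sampled along the same theta axis.

tumor_gene_sets <- function() {
  epi_markers <- c("Cdh1", "Epcam", "Cldn4", "Cldn7", "Tacstd2", "Esrp1",
                   "Krt8", "Krt18", "Ocln", "Dsp")
  mhc_genes <- c("H2-K1", "H2-D1", "B2m", "H2-Aa", "H2-Ab1", "H2-Eb1", "Cd74")
  mes_markers <- c("Vim", "Snai1", "Twist1", "Zeb1", "Gpnmb", "Mmp11", "Fn1",
                   "Cdh2", "S100a4", "Mmp2")
  gs76_epi_extra <- sprintf("Emt76e%02d", 1:40)
  gs76_mes_extra <- sprintf("Emt76m%02d", 1:19)
  list(epi_markers = epi_markers, mhc_genes = mhc_genes,
       mes_markers = mes_markers,
       gs76_epi_extra = gs76_epi_extra, gs76_mes_extra = gs76_mes_extra,
       # 10 + 7 + 40 + 19 = 76 genes, anchored on Cdh1
       gs76_genes = c(epi_markers, mhc_genes, gs76_epi_extra, gs76_mes_extra),
       epithelial_genes = c(epi_markers, mhc_genes, gs76_epi_extra),
       mesenchymal_genes = c(mes_markers, gs76_mes_extra))
}

immune_marker_map <- function() {
  list(
    CD8_cytotoxic = c("Cd3e", "Cd3d", "Cd8a", "Gzmb"),
    CD8_Lef1      = c("Cd3e", "Cd3d", "Cd8a", "Lef1", "Tcf7"),
    CD4_T         = c("Cd3e", "Cd3d", "Cd4"),
    Treg          = c("Cd3e", "Cd4", "Foxp3", "Ctla4", "Ikzf2"),
    NK            = c("Nkg7", "Ncr1", "Klrd1"),
    B_MHCII       = c("Cd19", "Cd79a", "Ms4a1"),
    Plasma        = c("Jchain", "Xbp1", "Ighg1", "Cd79a"),
    Breg          = c("Cd19", "Cd79a", "Il2ra", "Cd69"),
    Macrophage    = c("Adgre1", "Cd68", "Lyz2", "Itgam")
  )
}

# Subtype mixing probabilities at the epithelial (p0) and mesenchymal (p1)
# extremes. Logits are interpolated linearly in theta between log(p0) and
# log(p1), so the configured mixes are hit exactly at both endpoints.
immune_composition_spec <- function() {
  data.frame(
    subtype = c("CD8_cytotoxic", "CD8_Lef1", "CD4_T", "Treg", "NK",
                "B_MHCII", "Plasma", "Breg", "Macrophage"),
    p0 = c(0.25, 0.08, 0.15, 0.05, 0.10, 0.14, 0.10, 0.03, 0.10),
    p1 = c(0.05, 0.08, 0.15, 0.18, 0.10, 0.18, 0.02, 0.12, 0.12),
    stringsAsFactors = FALSE
  )
}

mito_gene_ids_default <- function() {
  c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3", "mt-Atp6", "mt-Atp8",
    "mt-Cytb", "mt-Nd3", "mt-Nd4", "mt-Nd4l", "mt-Nd5", "mt-Nd6")
}

#' Generate the ground truth of a synthetic tumor-microenvironment study
#'
#' Draws all generative parameters once: per-gene negative-binomial baseline
#' means and dispersions, per-gene log2-fold slopes versus the EMT parameter
#' theta, immune subtype mixing logits, effector-gene slopes, and the gene
#' universe itself (program genes, a 76-gene signature with Cdh1 anchor,
#' immune markers, mitochondrial genes and filler genes; 2,000 genes by
#' default). Everything downstream (tumor cells, immune cells, reference
#' panel) is simulated from this object.
#'
#' @param n_clones number of tumor clones (>= 2); with 5 clones they are
#'   named E, EM1, EM2, EM3, M. Clone thetas are evenly spaced on `[0, 1]`
#'   unless overridden.
#' @param seed integer seed; the same seed yields an identical truth object.
#' @param overrides named list overriding generator parameters. Recognized
#'   names: `theta` (per-clone EMT parameter), `n_genes` (default 2000),
#'   `size_factor_sd` (log-normal size factor sd, default 0.3),
#'   `qc_fail_fraction` (fraction of planted QC-failing cells, default 0.02),
#'   `panel_noise_sd` (log-scale noise of the bulk panel, default 0.25).
#' @return An object of class `SyntheticTruth`.
#' @export
generate_truth <- function(n_clones = 5L, seed = 1L, overrides = list()) {
  if (!is.numeric(n_clones) || length(n_clones) != 1 || n_clones < 2) {
    stop("n_clones must be a single integer >= 2")
  }
  n_clones <- as.integer(n_clones)
  known <- c("theta", "n_genes", "size_factor_sd", "qc_fail_fraction",
             "panel_noise_sd")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))

  theta <- overrides$theta %||% seq(0, 1, length.out = n_clones)
  if (length(theta) != n_clones || any(theta < 0 | theta > 1)) {
    stop("theta must give one value in [0,1] per clone")
  }
  n_genes <- as.integer(overrides$n_genes %||% 2000L)
  clone_names <- if (n_clones == 5) {
    c("E", "EM1", "EM2", "EM3", "M")
  } else {
    sprintf("clone%02d", seq_len(n_clones))
  }

  gs <- tumor_gene_sets()
  marker_map <- immune_marker_map()
  effector_genes <- c("Gzmb", "Gzma", "Prf1", "Ccr5", "Cxcr6", "Ifng")
  mito_genes <- mito_gene_ids_default()
  immune_genes <- unique(c(unlist(marker_map), effector_genes, "Ptprc"))
  named_genes <- unique(c(gs$epithelial_genes, gs$mesenchymal_genes,
                          immune_genes, mito_genes))
  n_filler <- n_genes - length(named_genes)
  if (n_filler < 0) stop("n_genes too small for the named gene blocks")
  filler <- sprintf("Gene%04d", seq_len(n_filler))
  gene_ids <- c(named_genes, filler)

  epi_program <- gs$epithelial_genes
  mes_program <- gs$mesenchymal_genes
  immune_only <- setdiff(immune_genes, c(epi_program, mes_program))

  with_seed(seed, {
    nb_mean_base <- stats::setNames(numeric(length(gene_ids)), gene_ids)
    nb_mean_base[filler] <- stats::rlnorm(n_filler, meanlog = log(0.5), sdlog = 1)
    nb_mean_base[epi_program] <- stats::runif(length(epi_program), 4, 8)
    nb_mean_base[mes_program] <- stats::runif(length(mes_program), 0.5, 1.2)
    nb_mean_base[mito_genes] <- stats::runif(length(mito_genes), 5, 9)
    nb_mean_base[immune_only] <- 0.02

    emt_effect <- stats::setNames(numeric(length(gene_ids)), gene_ids)
    emt_effect[epi_program] <- stats::runif(length(epi_program), -3, -2)
    emt_effect[mes_program] <- stats::runif(length(mes_program), 2, 3)

    nb_dispersion <- stats::setNames(stats::runif(length(gene_ids), 0.8, 2.5),
                                     gene_ids)

    immune_mean_base <- stats::setNames(rep(0.05, length(gene_ids)), gene_ids)
    immune_mean_base[filler] <- stats::rlnorm(n_filler, meanlog = log(0.4), sdlog = 1)
    immune_mean_base[mito_genes] <- stats::runif(length(mito_genes), 4, 7)
    immune_mean_base["Ptprc"] <- 5

    marker_genes <- unique(unlist(marker_map))
    marker_level <- stats::setNames(stats::runif(length(marker_genes), 4, 8),
                                    marker_genes)
    effector_level <- stats::setNames(stats::runif(length(effector_genes), 4, 7),
                                      effector_genes)
    effector_effect <- stats::setNames(stats::runif(length(effector_genes), -3, -2),
                                       effector_genes)

    comp <- immune_composition_spec()
    comp$base_logit <- log(comp$p0)
    comp$logit_slope <- log(comp$p1) - log(comp$p0)

    structure(list(
      clone_names = clone_names, theta = theta, gene_ids = gene_ids,
      nb_mean_base = nb_mean_base, nb_dispersion = nb_dispersion,
      emt_effect = emt_effect,
      immune_mean_base = immune_mean_base, marker_level = marker_level,
      effector_level = effector_level, effector_effect = effector_effect,
      composition = comp,
      gs76_genes = gs$gs76_genes, anchor_gene = "Cdh1",
      epithelial_genes = gs$epithelial_genes,
      mesenchymal_genes = gs$mesenchymal_genes,
      marker_map = marker_map, effector_genes = effector_genes,
      mito_gene_ids = mito_genes, filler_genes = filler,
      size_factor_sd = overrides$size_factor_sd %||% 0.3,
      qc_fail_fraction = overrides$qc_fail_fraction %||% 0.02,
      panel_noise_sd = overrides$panel_noise_sd %||% 0.25,
      seed = as.integer(seed)
    ), class = "SyntheticTruth")
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("<SyntheticTruth> %d clones (theta %s), %d genes, seed %d\n",
              length(x$clone_names),
              paste(format(x$theta, digits = 2), collapse = ", "),
              length(x$gene_ids), x$seed))
  invisible(x)
}

#' Expected tumor-cell expression profile at a given EMT parameter
#'
#' Returns the configured negative-binomial mean of every gene at EMT
#' parameter `theta`: `nb_mean_base * 2^(emt_effect * theta)` (before
#' per-cell size factors). Epithelial-program means are non-increasing and
#' mesenchymal-program means non-decreasing in theta by construction.
#'
#' @param truth a [generate_truth()] object.
#' @param theta scalar in `[0, 1]`.
#' @return Named numeric vector over the gene universe.
#' @export
tumor_mean_profile <- function(truth, theta) {
  stopifnot(inherits(truth, "SyntheticTruth"), theta >= 0, theta <= 1)
  truth$nb_mean_base * 2^(truth$emt_effect * theta)
}

#' Expected immune-cell expression profile for one subtype at a given theta
#'
#' Baseline immune expression with the subtype's marker genes raised to
#' their marker level; in cytotoxic CD8 and NK cells the effector genes are
#' set to `effector_level * 2^(effector_effect * theta)` (declining in
#' theta).
#'
#' @inheritParams tumor_mean_profile
#' @param subtype one of the subtype names in `truth$marker_map`.
#' @return Named numeric vector over the gene universe.
#' @export
immune_mean_profile <- function(truth, subtype, theta) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (!subtype %in% names(truth$marker_map)) {
    stop("unknown immune subtype: ", subtype)
  }
  mu <- truth$immune_mean_base
  mk <- truth$marker_map[[subtype]]
  mu[mk] <- truth$marker_level[mk]
  if (subtype %in% c("CD8_cytotoxic", "NK")) {
    eff <- truth$effector_genes
    mu[eff] <- truth$effector_level[eff] * 2^(truth$effector_effect[eff] * theta)
  }
  mu
}

#' Per-clone immune subtype mixing probabilities
#'
#' Softmax of logits linear in theta; each row sums to one, and the
#' configured endpoint mixes are reproduced exactly at theta = 0 and 1.
#'
#' @param truth a [generate_truth()] object.
#' @param theta vector of EMT parameters; defaults to the clone thetas.
#' @return Matrix `length(theta)` x subtypes of probabilities.
#' @export
composition_probs <- function(truth, theta = truth$theta) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  comp <- truth$composition
  logits <- outer(theta, comp$logit_slope) +
    matrix(comp$base_logit, length(theta), nrow(comp), byrow = TRUE)
  p <- exp(logits)
  p <- p / rowSums(p)
  dimnames(p) <- list(if (length(theta) == length(truth$theta) &&
                          isTRUE(all.equal(theta, truth$theta)))
                        truth$clone_names else NULL,
                      comp$subtype)
  p
}

# Shared count sampler: mu is genes x cells, dispersion per gene.
sample_nb_counts <- function(mu, dispersion) {
  n <- length(mu)
  counts <- stats::rnbinom(n, mu = as.vector(mu),
                           size = rep(dispersion, ncol(mu)))
  matrix(counts, nrow = nrow(mu), dimnames = dimnames(mu))
}

# Plant QC-failing cells: shrink total signal below the UMI threshold and
# inflate mitochondrial content above the mito-fraction threshold.
plant_qc_failures <- function(mu, mito_idx, n_fail) {
  fail_idx <- integer(0)
  if (n_fail > 0 && ncol(mu) > 0) {
    fail_idx <- seq_len(min(n_fail, ncol(mu)))
    mu[, fail_idx] <- mu[, fail_idx] * 0.04
    mu[mito_idx, fail_idx] <- mu[mito_idx, fail_idx] * 12
  }
  list(mu = mu, fail_idx = fail_idx)
}

#' Simulate tumor-compartment counts along the EMT gradient
#'
#' For each clone, per-cell counts are drawn gene-wise from a negative
#' binomial with mean `nb_mean_base * 2^(emt_effect * theta)` scaled by a
#' log-normal per-cell size factor. A configured fraction of cells per clone
#' is planted as QC failures (low total UMI, high mitochondrial fraction) so
#' that QC filtering is exercisable on synthetic data.
#'
#' @param truth a [generate_truth()] object.
#' @param n_cells_per_clone non-negative cell count per clone.
#' @param seed integer seed; identical seeds give bit-identical matrices.
#' @return A [count_matrix()] whose `sample_of_cell` holds the clone label;
#'   barcodes of planted QC-failing cells are in `attr(, "planted_fail")`.
#' @export
simulate_tumor_counts <- function(truth, n_cells_per_clone = 500L, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (!is.numeric(n_cells_per_clone) || n_cells_per_clone < 0) {
    stop("n_cells_per_clone must be >= 0")
  }
  n <- as.integer(n_cells_per_clone)
  mito_idx <- match(truth$mito_gene_ids, truth$gene_ids)
  with_seed(seed, {
    blocks <- vector("list", length(truth$clone_names))
    labels <- character(0)
    barcodes <- character(0)
    fail_barcodes <- character(0)
    for (i in seq_along(truth$clone_names)) {
      clone <- truth$clone_names[i]
      bc <- if (n > 0) sprintf("%s_cell%04d", clone, seq_len(n)) else character(0)
      if (n == 0) {
        blocks[[i]] <- matrix(0, nrow = length(truth$gene_ids), ncol = 0,
                              dimnames = list(truth$gene_ids, NULL))
        next
      }
      sf <- stats::rlnorm(n, meanlog = 0, sdlog = truth$size_factor_sd)
      prof <- tumor_mean_profile(truth, truth$theta[i])
      mu <- outer(prof, sf)
      planted <- plant_qc_failures(mu, mito_idx,
                                   floor(truth$qc_fail_fraction * n))
      dimnames(planted$mu) <- list(truth$gene_ids, bc)
      blocks[[i]] <- sample_nb_counts(planted$mu, truth$nb_dispersion)
      labels <- c(labels, rep(clone, n))
      barcodes <- c(barcodes, bc)
      fail_barcodes <- c(fail_barcodes, bc[planted$fail_idx])
    }
    counts <- do.call(cbind, blocks)
    cm <- count_matrix(counts, gene_ids = truth$gene_ids, barcodes = barcodes,
                       sample_of_cell = if (length(labels)) labels else character(0),
                       mito_flag = truth$gene_ids %in% truth$mito_gene_ids)
    attr(cm, "planted_fail") <- fail_barcodes
    cm
  })
}

#' Simulate immune-compartment (CD45+) counts along the EMT gradient
#'
#' Each cell's subtype is drawn from the clone's multinomial mix (logits
#' linear in theta: cytotoxic CD8 and plasma cells decline, Tregs and
#' regulatory-like B cells rise); subtype-defining markers are expressed in
#' the matching subtype, and effector genes in cytotoxic CD8 and NK cells
#' decline with theta.
#'
#' @inheritParams simulate_tumor_counts
#' @return A list with elements `matrix` (a [count_matrix()], clone label in
#'   `sample_of_cell`) and `subtype_of_cell` (named character vector, one
#'   subtype per barcode).
#' @export
simulate_immune_counts <- function(truth, n_cells_per_clone = 2000L, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (!is.numeric(n_cells_per_clone) || n_cells_per_clone < 0) {
    stop("n_cells_per_clone must be >= 0")
  }
  n <- as.integer(n_cells_per_clone)
  subtypes <- truth$composition$subtype
  probs <- composition_probs(truth)
  mito_idx <- match(truth$mito_gene_ids, truth$gene_ids)
  with_seed(seed, {
    blocks <- vector("list", length(truth$clone_names))
    labels <- character(0); barcodes <- character(0)
    subtype_of_cell <- character(0); fail_barcodes <- character(0)
    for (i in seq_along(truth$clone_names)) {
      clone <- truth$clone_names[i]
      if (n == 0) {
        blocks[[i]] <- matrix(0, nrow = length(truth$gene_ids), ncol = 0,
                              dimnames = list(truth$gene_ids, NULL))
        next
      }
      bc <- sprintf("%s_imm%05d", clone, seq_len(n))
      st_idx <- sample.int(length(subtypes), n, replace = TRUE, prob = probs[i, ])
      profiles <- vapply(subtypes, function(s)
        immune_mean_profile(truth, s, truth$theta[i]),
        numeric(length(truth$gene_ids)))
      sf <- stats::rlnorm(n, meanlog = 0, sdlog = truth$size_factor_sd)
      mu <- profiles[, st_idx, drop = FALSE] *
        rep(sf, each = length(truth$gene_ids))
      planted <- plant_qc_failures(mu, mito_idx,
                                   floor(truth$qc_fail_fraction * n))
      dimnames(planted$mu) <- list(truth$gene_ids, bc)
      blocks[[i]] <- sample_nb_counts(planted$mu, truth$nb_dispersion)
      labels <- c(labels, rep(clone, n))
      barcodes <- c(barcodes, bc)
      subtype_of_cell <- c(subtype_of_cell,
                           stats::setNames(subtypes[st_idx], bc))
      fail_barcodes <- c(fail_barcodes, bc[planted$fail_idx])
    }
    counts <- do.call(cbind, blocks)
    cm <- count_matrix(counts, gene_ids = truth$gene_ids, barcodes = barcodes,
                       sample_of_cell = if (length(labels)) labels else character(0),
                       mito_flag = truth$gene_ids %in% truth$mito_gene_ids)
    attr(cm, "planted_fail") <- fail_barcodes
    list(matrix = cm, subtype_of_cell = subtype_of_cell)
  })
}

#' Simulate a bulk reference panel spanning the EMT axis
#'
#' Samples are placed at evenly spaced theta values covering `[0, 1]`
#' (both endpoints included). The expected expression profile at each theta
#' is library-size normalized to counts per million, then each value is
#' `log2(1 + cpm(gene, theta) * exp(noise))` with log-normal multiplicative
#' noise - log2 expression on a TPM-like per-library scale, directly
#' comparable to the log2-CPM pseudobulk of [pseudobulk()]. The default
#' panel size is 81 samples, the size of the untreated murine mammary tumor
#' panel the analysis emulates.
#'
#' @param truth a [generate_truth()] object.
#' @param n_samples number of panel samples (>= 2).
#' @param seed integer seed.
#' @return An object of class `ReferencePanel`: `sample_ids`, `gene_ids`,
#'   `values` (samples x genes log2 expression), `scaled_flag`, and the
#'   per-sample `theta` used for generation.
#' @export
simulate_reference_panel <- function(truth, n_samples = 81L, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("n_samples must be >= 2")
  }
  n_samples <- as.integer(n_samples)
  theta_s <- seq(0, 1, length.out = n_samples)
  with_seed(seed, {
    g <- length(truth$gene_ids)
    mu <- vapply(theta_s, function(th) {
      prof <- tumor_mean_profile(truth, th)
      1e6 * prof / sum(prof)
    }, numeric(g))
    noise <- matrix(stats::rnorm(g * n_samples, 0, truth$panel_noise_sd),
                    nrow = g)
    vals <- t(log2(1 + mu * exp(noise)))
    sample_ids <- sprintf("panel%03d", seq_len(n_samples))
    dimnames(vals) <- list(sample_ids, truth$gene_ids)
    structure(list(sample_ids = sample_ids, gene_ids = truth$gene_ids,
                   values = vals, scaled_flag = FALSE, theta = theta_s),
              class = "ReferencePanel")
  })
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat(sprintf("<ReferencePanel> %d samples x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$scaled_flag) "gene-wise z-scaled" else "log2 scale"))
  invisible(x)
}

#' Gene-wise z-scale a reference panel
#'
#' Standardizes each gene (column) to mean 0 / population sd 1 across
#' samples; constant genes become zero columns.
#'
#' @param panel a [simulate_reference_panel()] object (or compatible).
#' @return The panel with scaled `values` and `scaled_flag = TRUE`.
#' @export
zscale_panel <- function(panel) {
  stopifnot(inherits(panel, "ReferencePanel"))
  panel$values <- t(row_zscale(t(panel$values)))
  panel$scaled_flag <- TRUE
  panel
}
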