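# Configuration and the end-to-end pipeline runner. The pipeline stages
# mirror the analysis order: simulate (or read) -> QC -> normalization ->
# EMT scoring with reference placement -> immune composition/trends ->
# gene-set enrichment. All outputs are TSV plus a JSON run manifest with
# content hashes, and every source of randomness derives from the single
# configured seed, so identical configs give byte-identical outputs.

pipeline_defaults <- function() {
  list(output = NULL, seed = 1L,
       n_clones = 5L, n_tumor_cells = 500L, n_immune_cells = 2000L,
       n_panel_samples = 81L,
       tumor_dir = NULL, immune_dir = NULL,
       qc_preset_tumor = "total", qc_preset_immune = "cd45",
       scale = 1e4, log2fc_threshold = 1.5, min_gene_overlap = 50,
       gmt = NULL, signature = NULL, mito_prefix = "mt-",
       stages = c("simulate", "qc", "score", "compose", "enrich"))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON, a YAML subset) configuration, rejects unknown
#' keys, fills defaults, and validates values. `output` is the only
#' required key.
#'
#' @param path configuration file path.
#' @return A validated list of class `PipelineConfig`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param cfg a named list of configuration values.
#' @export
validate_config <- function(cfg) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, cfg)
  if (is.null(out$output)) stop("missing required config key: output")
  if (!is.numeric(out$seed) || out$seed < 0) {
    stop("seed must be a non-negative integer")
  }
  out$seed <- as.integer(out$seed)
  bad_stage <- setdiff(out$stages, defaults$stages)
  if (length(bad_stage)) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  }
  for (key in c("tumor_dir", "immune_dir", "gmt", "signature")) {
    if (!is.null(out[[key]]) && !file.exists(out[[key]])) {
      stop("config key ", key, " points to a missing path: ", out[[key]])
    }
  }
  structure(out, class = "PipelineConfig")
}

#' Serialize a pipeline configuration to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param cfg a `PipelineConfig`.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages against synthetic data (generated from
#' the configured seed) or against 10x-style input directories when
#' `tumor_dir`/`immune_dir` are set. Outputs land in `cfg$output`:
#' QC reports, pseudobulk EMT score tables with reference placement, the
#' per-sample EMT trend test, a Tacstd2-vs-score correlation, immune
#' composition and trend tables, effector dot-plot statistics, pathway
#' enrichment z-scores, and `manifest.json` listing every file with its
#' MD5 content hash alongside the seed and parameters.
#'
#' @param cfg a `PipelineConfig` from [load_config()]/[validate_config()].
#' @param stages subset of stages to run (default: from the config).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, stages = cfg$stages) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  row_counts <- list()
  truth <- generate_truth(cfg$n_clones, seed = cfg$seed)
  sig <- if (is.null(cfg$signature)) default_signature(truth) else
    read_signature_tsv(cfg$signature)
  panel <- simulate_reference_panel(truth, cfg$n_panel_samples,
                                    seed = cfg$seed + 3L)

  tumor <- NULL; immune <- NULL; subtype_truth <- NULL
  if ("simulate" %in% stages) {
    tumor <- simulate_tumor_counts(truth, cfg$n_tumor_cells,
                                   seed = cfg$seed + 1L)
    imm <- simulate_immune_counts(truth, cfg$n_immune_cells,
                                  seed = cfg$seed + 2L)
    immune <- imm$matrix
    subtype_truth <- imm$subtype_of_cell
    write_tenx(tumor, file.path(cfg$output, "tumor_tenx"))
    write_tenx(immune, file.path(cfg$output, "immune_tenx"))
    files <- c(files,
               file.path(cfg$output, "tumor_tenx",
                         c("matrix.mtx", "features.tsv", "barcodes.tsv", "cells.tsv")),
               file.path(cfg$output, "immune_tenx",
                         c("matrix.mtx", "features.tsv", "barcodes.tsv", "cells.tsv")))
  }
  if (!is.null(cfg$tumor_dir)) tumor <- read_tenx(cfg$tumor_dir, cfg$mito_prefix)
  if (!is.null(cfg$immune_dir)) immune <- read_tenx(cfg$immune_dir, cfg$mito_prefix)
  if (is.null(tumor)) stop("no tumor input: enable the simulate stage or set tumor_dir")

  if ("qc" %in% stages) {
    qct <- qc_filter(tumor, qc_params(cfg$qc_preset_tumor))
    tumor <- qct$matrix
    rep_t <- cbind(compartment = "tumor", qct$report)
    rep_i <- NULL
    if (!is.null(immune)) {
      qci <- qc_filter(immune, qc_params(cfg$qc_preset_immune))
      immune <- qci$matrix
      rep_i <- cbind(compartment = "immune", qci$report)
    }
    qc_path <- write_tsv(rbind(rep_t, rep_i),
                         file.path(cfg$output, "qc_report.tsv"))
    files <- c(files, qc_path)
    row_counts$qc_tumor_cells <- ncol(tumor$counts)
    row_counts$qc_immune_cells <- if (is.null(immune)) NA else ncol(immune$counts)
  }

  scores_tab <- NULL
  if ("score" %in% stages) {
    pb <- pseudobulk(tumor, log2 = TRUE)
    placed <- place_on_reference(pb, panel, sig,
                                 min_overlap = cfg$min_gene_overlap)
    scores_tab <- placed$scores
    files <- c(files, write_tsv(scores_tab,
                                file.path(cfg$output, "emt_scores.tsv")))
    row_counts$scored_units <- nrow(scores_tab)
    query <- scores_tab[scores_tab$is_query, ]
    ord <- order(-query$harmonized_76gs)  # rank 0 = most epithelial
    emt_rank <- stats::setNames(seq_along(ord) - 1L, query$unit_id[ord])
    if (nrow(query) >= 3) {
      trend <- trend_test(query$harmonized_76gs, emt_rank[query$unit_id])
      files <- c(files, write_tsv(
        data.frame(statistic = "harmonized_76gs_vs_rank", slope = trend$slope,
                   intercept = trend$intercept, p_value = trend$p_value,
                   n = trend$n),
        file.path(cfg$output, "emt_trend.tsv")))
    }

    logn_t <- lognormalize(tumor, cfg$scale)
    cell_scores <- score_76gs(logn_t, sig)
    tac <- gene_score_correlation(logn_t, "Tacstd2", cell_scores)
    files <- c(files, write_tsv(
      data.frame(gene = "Tacstd2", r = tac$r, p_value = tac$p_value, n = tac$n),
      file.path(cfg$output, "tacstd2_correlation.tsv")))

    gm <- vapply(unique(tumor$sample_of_cell), function(s) {
      log2(1 + Matrix::rowMeans(tumor$counts[, tumor$sample_of_cell == s,
                                             drop = FALSE]))
    }, numeric(nrow(tumor$counts)))
    vg <- select_variable_genes(gm, cfg$log2fc_threshold)
    files <- c(files, {
      p <- file.path(cfg$output, "variable_genes.tsv")
      writeLines(c("gene", vg), p); p
    })
    row_counts$variable_genes <- length(vg)
  } else {
    emt_rank <- stats::setNames(seq_along(truth$clone_names) - 1L,
                                truth$clone_names)
  }

  ann <- NULL
  if ("compose" %in% stages && !is.null(immune)) {
    logn_i <- lognormalize(immune, cfg$scale)
    ann <- annotate_by_markers(logn_i, truth$marker_map)
    rank_for <- if (!is.null(scores_tab)) {
      q <- scores_tab[scores_tab$is_query, ]
      stats::setNames(rank(-q$harmonized_76gs) - 1L, q$unit_id)
    } else {
      stats::setNames(seq_along(truth$clone_names) - 1L, truth$clone_names)
    }
    comp <- composition_table(ann, emt_rank = rank_for)
    comp_df <- data.frame(sample = rownames(comp$proportions),
                          emt_rank = as.integer(comp$emt_rank),
                          n_cells = comp$n_cells,
                          comp$proportions, check.names = FALSE)
    files <- c(files, write_tsv(comp_df,
                                file.path(cfg$output, "composition.tsv")))
    trends <- do.call(rbind, lapply(colnames(comp$proportions), function(st) {
      tr <- trend_test(comp$proportions[, st], comp$emt_rank)
      data.frame(subtype = st, slope = tr$slope, p_value = tr$p_value,
                 n = tr$n)
    }))
    files <- c(files, write_tsv(trends,
                                file.path(cfg$output, "composition_trends.tsv")))
    cd8 <- ann$barcode[ann$subtype == "CD8_cytotoxic"]
    if (length(cd8) >= 2) {
      idx <- match(cd8, logn_i$unit_ids)
      sub <- normalized_matrix(logn_i$values[, idx, drop = FALSE],
                               "lognorm-per-cell",
                               sample_of_cell = logn_i$sample_of_cell[idx])
      eff <- dotplot_stats(sub, c("Gzmb", "Ccr5", "Cxcr6", "Prf1"))
      files <- c(files, write_tsv(eff,
                                  file.path(cfg$output, "effector_dotplot.tsv")))
    }
    row_counts$annotated_cells <- nrow(ann)
  }

  if ("enrich" %in% stages && !is.null(immune)) {
    gmt_path <- cfg$gmt %||% system.file("extdata", "synthetic_hallmark.gmt",
                                         package = "emtscape")
    sets <- load_gmt(gmt_path)
    logn_i <- lognormalize(immune, cfg$scale)
    if (is.null(ann)) ann <- annotate_by_markers(logn_i, truth$marker_map)
    nk <- ann$barcode[ann$subtype == "NK"]
    if (length(nk) >= 2) {
      idx <- match(nk, logn_i$unit_ids)
      sub <- normalized_matrix(logn_i$values[, idx, drop = FALSE],
                               "lognorm-per-cell",
                               sample_of_cell = logn_i$sample_of_cell[idx])
      z <- wmw_enrichment_z(sub, sets)
      zdf <- data.frame(set = rownames(z), unclass(z), check.names = FALSE)
      files <- c(files, write_tsv(zdf,
                                  file.path(cfg$output, "enrichment_z.tsv")))
      row_counts$enriched_sets <- nrow(z)
    }
  }

  manifest <- list(
    package = "emtscape",
    version = as.character(utils::packageVersion("emtscape")),
    seed = cfg$seed,
    parameters = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    stages_run = stages,
    row_counts = row_counts,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(cfg$output, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
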