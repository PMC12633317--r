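#' Construct an EMT gene signature
#'
#' Holds the 76-gene signature with its anchor gene (Cdh1, the canonical
#' epithelial marker the weights are anchored on) and a disjoint
#' epithelial/mesenchymal partition used by the KS and MLR scores.
#'
#' @param gs76_genes character vector of signature genes for the 76-gene
#'   score.
#' @param anchor_gene the anchor (default `"Cdh1"`).
#' @param epithelial_genes,mesenchymal_genes disjoint gene lists.
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(gs76_genes, anchor_gene = "Cdh1",
                           epithelial_genes, mesenchymal_genes) {
  gs76_genes <- unique(as.character(gs76_genes))
  epithelial_genes <- unique(as.character(epithelial_genes))
  mesenchymal_genes <- unique(as.character(mesenchymal_genes))
  overlap <- intersect(epithelial_genes, mesenchymal_genes)
  if (length(overlap)) {
    stop("epithelial and mesenchymal gene lists must be disjoint; shared: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  if (!length(gs76_genes)) stop("gs76_genes must be non-empty")
  structure(list(gs76_genes = gs76_genes, anchor_gene = anchor_gene,
                 epithelial_genes = epithelial_genes,
                 mesenchymal_genes = mesenchymal_genes),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("<GeneSignature> %d-gene signature (anchor %s), %d epithelial / %d mesenchymal\n",
              length(x$gs76_genes), x$anchor_gene,
              length(x$epithelial_genes), length(x$mesenchymal_genes)))
  invisible(x)
}

#' The signature matching a synthetic truth object
#'
#' @param truth a [generate_truth()] object.
#' @return A [gene_signature()] over the generator's gene analogs.
#' @export
default_signature <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  gene_signature(truth$gs76_genes, truth$anchor_gene,
                 truth$epithelial_genes, truth$mesenchymal_genes)
}

#' Read a gene signature from a two-column TSV
#'
#' Expected columns: `gene`, `class` with class in
#' `{epithelial, mesenchymal, 76gs, anchor}`. A row of class `anchor`
#' overrides the default anchor gene.
#'
#' @param path TSV file path.
#' @param anchor_gene fallback anchor when no `anchor` row is present.
#' @return A [gene_signature()].
#' @export
read_signature_tsv <- function(path, anchor_gene = "Cdh1") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene", "class") %in% names(df))) {
    stop("signature TSV needs columns 'gene' and 'class': ", path)
  }
  bad <- setdiff(unique(df$class), c("epithelial", "mesenchymal", "76gs", "anchor"))
  if (length(bad)) stop("unknown signature class(es): ", paste(bad, collapse = ", "))
  anchors <- df$gene[df$class == "anchor"]
  if (length(anchors) > 1) stop("at most one anchor row allowed")
  gene_signature(df$gene[df$class %in% c("76gs", "anchor")],
                 if (length(anchors)) anchors else anchor_gene,
                 df$gene[df$class == "epithelial"],
                 df$gene[df$class == "mesenchymal"])
}

#' Write a gene signature as a two-column TSV
#'
#' @param sig a [gene_signature()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_signature_tsv <- function(sig, path) {
  stopifnot(inherits(sig, "GeneSignature"))
  df <- rbind(
    data.frame(gene = sig$anchor_gene, class = "anchor"),
    data.frame(gene = setdiff(sig$gs76_genes, sig$anchor_gene), class = "76gs"),
    data.frame(gene = sig$epithelial_genes, class = "epithelial"),
    data.frame(gene = sig$mesenchymal_genes, class = "mesenchymal"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
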