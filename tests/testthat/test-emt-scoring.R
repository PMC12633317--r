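test_that("gene_signature enforces a disjoint epithelial/mesenchymal split", {
  expect_error(gene_signature(c("a", "b"), "a", c("a", "x"), c("x", "y")),
               "disjoint")
  sig <- gene_signature(c("a", "b"), "a", c("a", "b"), c("c", "d"))
  expect_s3_class(sig, "GeneSignature")
  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(sig, path)
  back <- read_signature_tsv(path)
  expect_setequal(back$gs76_genes, sig$gs76_genes)
  expect_equal(back$anchor_gene, "a")
  expect_equal(back$epithelial_genes, sig$epithelial_genes)
  expect_equal(back$mesenchymal_genes, sig$mesenchymal_genes)
})

test_that("76GS score equals the anchor-correlation weighted-sum oracle", {
  # 4 units, anchor + 3 signature genes with hand-checkable correlations
  v <- rbind(anchor = c(1, 2, 3, 4),
             s1 = c(2, 4, 6, 8),
             s2 = c(4, 3, 2, 1),
             s3 = c(1, 1, 2, 2),
             other = c(5, 5, 5, 5))
  colnames(v) <- sprintf("u%d", 1:4)
  sig <- gene_signature(c("anchor", "s1", "s2", "s3"), "anchor",
                        c("anchor", "s1"), c("s2", "s3"))
  got <- score_76gs(toy_norm_matrix(v), sig)
  # brute force: Pearson weights by direct formula, then weighted sums
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  w <- vapply(c("anchor", "s1", "s2", "s3"),
              function(g) pearson(v[g, ], v["anchor", ]), numeric(1))
  raw <- colSums(v[c("anchor", "s1", "s2", "s3"), ] * w)
  expect_equal(got, raw - mean(raw))
  expect_lt(abs(sum(got)), 1e-8)
})

test_that("76GS degenerate inputs error and missing genes warn", {
  v <- rbind(anchor = c(1, 1, 1), s1 = c(1, 2, 3))
  colnames(v) <- c("u1", "u2", "u3")
  sig <- gene_signature(c("anchor", "s1"), "anchor", "anchor", "s1")
  expect_error(score_76gs(toy_norm_matrix(v), sig), "constant")
  v2 <- rbind(anchor = c(1, 2, 3), s1 = c(1, 2, 4))
  colnames(v2) <- c("u1", "u2", "u3")
  expect_error(score_76gs(toy_norm_matrix(v2[, 1:2]), sig), "3 units")
  sig_extra <- gene_signature(c("anchor", "s1", "ghost"), "anchor",
                              "anchor", "s1")
  expect_warning(score_76gs(toy_norm_matrix(v2), sig_extra), "ghost")
})

test_that("KS score matches hand cases and stays within [-1, 1]", {
  sig <- gene_signature("e1", "e1",
                        c("e1", "e2"), c("m1", "m2"))
  # identical multisets -> 0
  v <- matrix(c(1, 2, 1, 2), ncol = 1,
              dimnames = list(c("e1", "e2", "m1", "m2"), "u1"))
  expect_equal(unname(score_ks(toy_norm_matrix(v), sig)), 0)
  # epithelial {0,0} vs mesenchymal {5,5} -> +1 (mesenchymal-positive sign)
  v2 <- matrix(c(0, 0, 5, 5), ncol = 1,
               dimnames = list(c("e1", "e2", "m1", "m2"), "u1"))
  expect_equal(unname(score_ks(toy_norm_matrix(v2), sig)), 1)
  # reversed -> -1
  v3 <- matrix(c(5, 5, 0, 0), ncol = 1,
               dimnames = list(c("e1", "e2", "m1", "m2"), "u1"))
  expect_equal(unname(score_ks(toy_norm_matrix(v3), sig)), -1)
  # missing-arm error names the missing genes
  sig_missing <- gene_signature("e1", "e1", c("e1", "e2"), c("m1", "zz"))
  v4 <- v2[c("e1", "e2", "m1"), , drop = FALSE]
  expect_error(score_ks(toy_norm_matrix(v4), sig_missing), "zz")
})

test_that("KS score equals the brute-force ECDF oracle on random instances", {
  set.seed(101)
  sig_for <- function(ne, nm) {
    gene_signature("e01", "e01",
                   sprintf("e%02d", seq_len(ne)), sprintf("m%02d", seq_len(nm)))
  }
  for (i in 1:200) {
    ne <- sample(2:12, 1); nm <- sample(2:12, 1)
    vals <- sample(0:6, ne + nm, replace = TRUE) + ifelse(runif(ne + nm) < 0.5, 0, 0.5)
    v <- matrix(vals, ncol = 1,
                dimnames = list(c(sprintf("e%02d", 1:ne), sprintf("m%02d", 1:nm)),
                                "u1"))
    got <- suppressMessages(score_ks(toy_norm_matrix(v), sig_for(ne, nm)))
    expect_identical(unname(got), ks_oracle(vals[1:ne], vals[-(1:ne)]))
    expect_gte(got, -1); expect_lte(got, 1)
  }
})

mlr_toy_training <- function(n_per_class = 20, sep = 3, noise = 0.3, seed = 7) {
  set.seed(seed)
  n <- 3 * n_per_class
  classes <- rep(c("E", "H", "M"), each = n_per_class)
  epi <- c(rep(sep, n_per_class), rep(0, n_per_class), rep(-sep, n_per_class)) +
    rnorm(n, 0, noise)
  mes <- -c(rep(sep, n_per_class), rep(0, n_per_class), rep(-sep, n_per_class)) +
    rnorm(n, 0, noise)
  # two epithelial and two mesenchymal genes realizing those predictor means
  v <- rbind(e1 = epi, e2 = epi, m1 = mes, m2 = mes)
  colnames(v) <- sprintf("t%03d", seq_len(n))
  list(x = normalized_matrix(v, "zscaled"), classes = classes)
}

test_that("MLR probabilities are proper and the E centroid scores epithelial", {
  tr <- mlr_toy_training()
  sig <- gene_signature("e1", "e1", c("e1", "e2"), c("m1", "m2"))
  # query: the E-class centroid plus one unit per class centroid
  q <- matrix(c(3, 3, -3, -3,
                0, 0, 0, 0,
                -3, -3, 3, 3), nrow = 4,
              dimnames = list(c("e1", "e2", "m1", "m2"), c("qE", "qH", "qM")))
  s <- score_mlr(normalized_matrix(q, "zscaled"), sig, tr$x, tr$classes)
  probs <- attr(s, "probabilities")
  expect_equal(unname(rowSums(probs)), rep(1, 3), tolerance = 1e-10)
  expect_true(all(s >= 0 & s <= 2))
  expect_lt(s[["qE"]], 0.5)
  expect_gt(s[["qM"]], 1.5)
  expect_true(s[["qE"]] < s[["qH"]] && s[["qH"]] < s[["qM"]])
  expect_error(score_mlr(normalized_matrix(q, "zscaled"), sig, tr$x,
                         rep(c("E", "H"), each = 30)),
               "missing: M")
})

test_that("MLR score recovers the EMT gradient on a synthetic panel", {
  tr <- truth5()
  pan <- simulate_reference_panel(tr, 31, seed = 21)
  sig <- default_signature(tr)
  x <- normalized_matrix(t(pan$values), "log2-pseudobulk")
  s <- score_mlr(x, sig, x, theta_classes(pan$theta))
  expect_gte(cor(s, pan$theta, method = "spearman"), 0.9)
})

test_that("harmonization flips KS and MLR onto the epithelial-high scale", {
  t <- emt_score_table(c("u1", "u2", "u3"),
                       score_76gs = c(1, 0, -1),
                       score_ks_raw = c(0.8, 0, -0.3),
                       score_mlr_raw = c(2, 1, 0))
  h <- harmonize_scores(t)
  expect_equal(h$harmonized_ks, c(-0.8, 0, 0.3))
  expect_equal(h$harmonized_mlr, c(0, 1, 2))
  expect_equal(h$harmonized_76gs, h$score_76gs)
  # involution on KS: flipping twice is the identity
  expect_equal(-(-t$score_ks_raw), t$score_ks_raw)
  # range-preserving reflection keeps MLR in [0, 2]
  expect_true(all(h$harmonized_mlr >= 0 & h$harmonized_mlr <= 2))
})

test_that("concordance matrix is a proper correlation matrix", {
  t <- harmonize_scores(emt_score_table(
    sprintf("u%d", 1:5),
    score_76gs = c(2, 1, 0, -1, -2),
    score_ks_raw = c(-0.9, -0.4, 0.1, 0.4, 0.8),
    score_mlr_raw = c(0.1, 0.6, 1.0, 1.5, 1.9)))
  cm <- concordance_matrix(t)
  expect_equal(diag(cm), setNames(rep(1, 3), colnames(cm)))
  expect_equal(cm, t(cm))
  expect_true(all(cm[upper.tri(cm)] > 0))
  t_const <- t; t_const$harmonized_ks <- 0
  expect_error(concordance_matrix(t_const), "harmonized_ks")
})

test_that("reference placement scales jointly and is exact for duplicated samples", {
  tr <- truth5()
  pan <- simulate_reference_panel(tr, 41, seed = 31)
  sig <- default_signature(tr)
  # query duplicated from two panel samples must receive their exact scores
  dup_ids <- c("panel010", "panel030")
  q <- t(pan$values[dup_ids, , drop = FALSE])
  colnames(q) <- c("dupA", "dupB")
  pl <- place_on_reference(normalized_matrix(q, "log2-pseudobulk"), pan, sig)
  sc <- pl$scores
  for (i in 1:2) {
    orig <- sc[sc$unit_id == dup_ids[i], ]
    dup <- sc[sc$unit_id == c("dupA", "dupB")[i], ]
    expect_equal(dup$harmonized_76gs, orig$harmonized_76gs, tolerance = 1e-10)
    expect_equal(dup$harmonized_ks, orig$harmonized_ks, tolerance = 1e-10)
    expect_equal(dup$harmonized_mlr, orig$harmonized_mlr, tolerance = 1e-10)
  }
  # joint scaling: each non-constant shared gene has mean 0, sd 1
  comb <- pl$combined$values
  nonconst <- apply(comb, 1, function(v) length(unique(v)) > 1)
  expect_lt(max(abs(rowMeans(comb[nonconst, ]))), 1e-10)
  sds <- apply(comb[nonconst, ], 1, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(sds - 1)), 1e-10)
  # insufficient overlap errors with the observed overlap size
  small <- q[1:10, , drop = FALSE]
  expect_error(place_on_reference(normalized_matrix(small, "log2-pseudobulk"),
                                  pan, sig), "overlap")
})
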