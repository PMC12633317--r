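test_that("generate_truth spaces clone thetas evenly and is deterministic", {
  tr <- truth5()
  expect_equal(tr$theta, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(tr$clone_names, c("E", "EM1", "EM2", "EM3", "M"))
  expect_false(anyDuplicated(tr$clone_names) > 0)
  tr2 <- generate_truth(5, seed = 1)
  expect_identical(tr, tr2)
  tr3 <- generate_truth(5, seed = 99)
  expect_false(identical(tr$nb_mean_base, tr3$nb_mean_base))
  expect_error(generate_truth(1), "n_clones")
  expect_error(generate_truth(5, overrides = list(nonsense = 1)), "unknown override")
})

test_that("truth invariants hold: dispersion positive, composition normalized", {
  tr <- truth5()
  expect_true(all(tr$nb_dispersion > 0))
  expect_true(all(tr$theta >= 0 & tr$theta <= 1))
  p <- composition_probs(tr)
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-12)
  p_fine <- composition_probs(tr, theta = seq(0, 1, by = 0.01))
  expect_true(all(abs(rowSums(p_fine) - 1) < 1e-12))
})

test_that("configured mean expression is monotone in theta per program", {
  tr <- truth5()
  grid <- seq(0, 1, by = 0.05)
  profiles <- vapply(grid, function(th) tumor_mean_profile(tr, th),
                     numeric(length(tr$gene_ids)))
  for (g in tr$epithelial_genes) {
    expect_true(all(diff(profiles[g, ]) <= 0), label = paste(g, "non-increasing"))
  }
  for (g in tr$mesenchymal_genes) {
    expect_true(all(diff(profiles[g, ]) >= 0), label = paste(g, "non-decreasing"))
  }
  # the Tacstd2 analog tracks the epithelial end of the spectrum
  expect_lt(tr$emt_effect["Tacstd2"], 0)
  expect_true(all(tr$emt_effect[c("H2-K1", "H2-Aa", "B2m")] < 0))
})

test_that("expected Treg fraction is non-decreasing and cytotoxic CD8 non-increasing in theta", {
  tr <- truth5()
  p <- composition_probs(tr, theta = seq(0, 1, by = 0.01))
  expect_true(all(diff(p[, "Treg"]) >= 0))
  expect_true(all(diff(p[, "CD8_cytotoxic"]) <= 0))
  expect_true(all(diff(p[, "Plasma"]) <= 0))
  expect_true(all(diff(p[, "Breg"]) >= 0))
})

test_that("tumor counts: determinism, empty case, epithelial dominance at theta=0", {
  tr <- truth5()
  m1 <- simulate_tumor_counts(tr, 50, seed = 7)
  m2 <- simulate_tumor_counts(tr, 50, seed = 7)
  expect_identical(m1$counts, m2$counts)
  m3 <- simulate_tumor_counts(tr, 50, seed = 8)
  expect_false(identical(m1$counts, m3$counts))

  m0 <- simulate_tumor_counts(tr, 0, seed = 1)
  expect_equal(ncol(m0$counts), 0)
  expect_equal(m0$gene_ids, tr$gene_ids)
  expect_error(simulate_tumor_counts(tr, -1), "n_cells_per_clone")

  # at theta = 0 the empirical epithelial-program mean must exceed the
  # mesenchymal-program mean given the configured NB means (3-sigma check)
  tr0 <- generate_truth(2, seed = 3,
                        overrides = list(size_factor_sd = 0,
                                         qc_fail_fraction = 0))
  m <- simulate_tumor_counts(tr0, 2000, seed = 4)
  e_cells <- m$sample_of_cell == "clone01"
  epi_mean <- mean(as.matrix(m$counts[tr0$epithelial_genes, e_cells]))
  mes_mean <- mean(as.matrix(m$counts[tr0$mesenchymal_genes, e_cells]))
  prof <- tumor_mean_profile(tr0, 0)
  expected_gap <- mean(prof[tr0$epithelial_genes]) - mean(prof[tr0$mesenchymal_genes])
  expect_gt(expected_gap, 0)
  expect_gt(epi_mean, mes_mean)
  expect_lt(abs((epi_mean - mes_mean) - expected_gap), expected_gap / 2)
})

test_that("sampled counts match negative-binomial mean and variance formulas", {
  tr <- generate_truth(2, seed = 5,
                       overrides = list(size_factor_sd = 0,
                                        qc_fail_fraction = 0))
  m <- simulate_tumor_counts(tr, 5000, seed = 6)
  cells <- m$sample_of_cell == "clone01"
  prof <- tumor_mean_profile(tr, 0)
  n <- sum(cells)
  for (g in c("Cdh1", "Vim", "Gene0005")) {
    x <- as.numeric(m$counts[g, cells])
    mu <- prof[[g]]
    size <- tr$nb_dispersion[[g]]
    v <- mu + mu^2 / size
    # 4-sigma Monte-Carlo tolerance; Var(sample variance) from exact NB
    # central moments computed by pmf summation (independent oracle)
    expect_lt(abs(mean(x) - mu), 4 * sqrt(v / n))
    kmax <- stats::qnbinom(1 - 1e-12, mu = mu, size = size)
    ks <- 0:kmax
    pmf <- stats::dnbinom(ks, mu = mu, size = size)
    m4 <- sum(pmf * (ks - mu)^4)
    var_of_var <- (m4 - v^2) / n
    expect_lt(abs(stats::var(x) - v), 4 * sqrt(var_of_var))
  }
})

test_that("immune counts: labels partition cells, composition near configured mix", {
  tr <- truth5()
  im <- simulate_immune_counts(tr, 300, seed = 9)
  expect_equal(sort(names(im$subtype_of_cell)), sort(im$matrix$barcodes))
  expect_true(all(im$subtype_of_cell %in% tr$composition$subtype))
  im2 <- simulate_immune_counts(tr, 300, seed = 9)
  expect_identical(im$matrix$counts, im2$matrix$counts)
  expect_identical(im$subtype_of_cell, im2$subtype_of_cell)

  # cytotoxic CD8 fraction at theta=0 within the exact binomial 99% interval
  im_big <- simulate_immune_counts(tr, 5000, seed = 10)
  e_cells <- im_big$matrix$sample_of_cell == "E"
  obs <- sum(im_big$subtype_of_cell[im_big$matrix$barcodes[e_cells]] ==
               "CD8_cytotoxic")
  p0 <- composition_probs(tr)["E", "CD8_cytotoxic"]
  lo <- stats::qbinom(0.005, 5000, p0)
  hi <- stats::qbinom(0.995, 5000, p0)
  expect_gte(obs, lo)
  expect_lte(obs, hi)
})

test_that("reference panel spans both EMT extremes and is reproducible", {
  tr <- truth5()
  pan <- simulate_reference_panel(tr, seed = 2)
  expect_equal(nrow(pan$values), 81)
  expect_equal(min(pan$theta), 0)
  expect_equal(max(pan$theta), 1)
  expect_false(anyNA(pan$values))
  expect_false(anyDuplicated(pan$gene_ids) > 0)
  pan2 <- simulate_reference_panel(tr, seed = 2)
  expect_identical(pan$values, pan2$values)
  expect_error(simulate_reference_panel(tr, 1), "n_samples")

  sc <- zscale_panel(pan)
  expect_true(sc$scaled_flag)
  nonconst <- apply(pan$values, 2, function(v) length(unique(v)) > 1)
  expect_lt(max(abs(colMeans(sc$values[, nonconst]))), 1e-8)
  sds <- apply(sc$values[, nonconst], 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(sds - 1)), 1e-8)
})

test_that("10x-style write/read round-trips and the MTX header is faithful", {
  tr <- truth5()
  m <- simulate_tumor_counts(tr, 20, seed = 11)
  d <- withr::local_tempdir()
  write_tenx(m, d)
  back <- read_tenx(d)
  expect_equal(as.matrix(back$counts), as.matrix(m$counts))
  expect_identical(back$gene_ids, m$gene_ids)
  expect_identical(back$barcodes, m$barcodes)
  expect_identical(back$sample_of_cell, m$sample_of_cell)
  expect_identical(back$mito_flag, m$mito_flag)

  # 3-gene x 2-cell toy: header declares dims and nnz equal to hand count
  toy <- count_matrix(matrix(c(5, 0, 1, 0, 0, 2), nrow = 3,
                             dimnames = list(c("a", "b", "mt-x"),
                                             c("c1", "c2"))))
  d2 <- withr::local_tempdir()
  write_tenx(toy, d2)
  lines <- readLines(file.path(d2, "matrix.mtx"))
  header <- lines[!startsWith(lines, "%")][1]
  expect_equal(scan(text = header, quiet = TRUE), c(3, 2, 3))

  # empty matrix round-trips with a 0-column header
  empty <- count_matrix(matrix(numeric(0), nrow = 2, ncol = 0,
                               dimnames = list(c("a", "b"), NULL)),
                        sample_of_cell = character(0))
  d3 <- withr::local_tempdir()
  write_tenx(empty, d3)
  back_empty <- read_tenx(d3)
  expect_equal(ncol(back_empty$counts), 0)
  expect_equal(back_empty$gene_ids, c("a", "b"))
})
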