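# Independent brute-force oracles used to validate the package's
# implementations on small random instances.

# Signed KS statistic by explicit ECDF evaluation over the pooled grid.
ks_oracle <- function(epi_values, mes_values) {
  grid <- sort(unique(c(epi_values, mes_values)))
  f_e <- vapply(grid, function(t) mean(epi_values <= t), numeric(1))
  f_m <- vapply(grid, function(t) mean(mes_values <= t), numeric(1))
  d_mes <- max(f_e - f_m)
  d_epi <- max(f_m - f_e)
  if (d_mes >= d_epi) d_mes else -d_epi
}

# Mann-Whitney U by exhaustive pairwise enumeration (wins + half-ties),
# converted to z with the closed-form tie-corrected normal approximation
# and continuity correction.
wmw_oracle <- function(in_values, out_values) {
  u <- 0
  for (a in in_values) {
    for (b in out_values) {
      u <- u + (a > b) + 0.5 * (a == b)
    }
  }
  n1 <- length(in_values); n2 <- length(out_values); n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(c(in_values, out_values))
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  d <- u - mu
  (d - 0.5 * sign(d)) / sqrt(sigma2)
}

# Independent per-cell application of the four printed QC inequalities.
qc_oracle_keep <- function(counts, mito_rows, min_umi, min_features,
                           max_mito, min_complexity) {
  apply(counts, 2, function(cell) {
    n_umi <- sum(cell)
    n_feat <- sum(cell > 0)
    mito_frac <- if (n_umi > 0) sum(cell[mito_rows]) / n_umi else 0
    cplx <- if (n_umi > 1) log10(max(n_feat, 1)) / log10(n_umi) else 0
    n_umi > min_umi && n_feat > min_features &&
      mito_frac < max_mito && cplx > min_complexity
  })
}

# Closed-form OLS slope/intercept and two-sided t-test p-value.
ols_oracle <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       p_value = 2 * stats::pt(-abs(tval), df = n - 2))
}
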