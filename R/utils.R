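`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Population (divide-by-n) standard deviation; the z-scaling convention used
# throughout the package.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Row-wise z-scaling with the population sd; constant rows map to all zeros.
row_zscale <- function(mat) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  cen <- mat - mu
  sdv <- sqrt(rowMeans(cen^2))
  out <- cen / sdv
  out[sdv == 0, ] <- 0
  out
}

# Coerce a NormalizedMatrix or plain matrix to a dense expression matrix
# (genes x units) plus its normalization kind.
as_expr_matrix <- function(x) {
  if (inherits(x, "NormalizedMatrix")) {
    list(values = as.matrix(x$values), kind = x$norm_kind,
         sample_of_cell = x$sample_of_cell)
  } else if (is.matrix(x) || inherits(x, "Matrix")) {
    list(values = as.matrix(x), kind = "unknown", sample_of_cell = NULL)
  } else {
    stop("expected a NormalizedMatrix or a matrix, got ", class(x)[1])
  }
}
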