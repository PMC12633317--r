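# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

truth5 <- function() fixture("truth5", function() generate_truth(5, seed = 1))

# A small normalized matrix with named genes/units for scoring tests.
toy_norm_matrix <- function(values, kind = "lognorm-per-cell") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("u%02d", seq_len(ncol(values)))
  }
  normalized_matrix(values, kind)
}
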