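# Small deterministic structures used across the suite.

cycle_matrix <- function(n) {
  C <- matrix(0L, n, n)
  for (k in seq_len(n)) C[k %% n + 1L, k] <- 1L
  C
}

complete_matrix <- function(n) matrix(1L, n, n)

# Random irreducible binary matrix of modest size, drawn through the
# package generator under a fixed seed.
random_irreducible <- function(n, p_c, seed) {
  generate_support_matrix(n, p_c, seed = seed, require_irreducible = TRUE,
                          max_attempts = 5000L)
}

tiny_cfg <- function(n_o, p_c_oo, a_over_b = 100, p_m = 0, ...) {
  scenario_config(n_o = n_o, p_c_oo = p_c_oo, a_over_b = a_over_b,
                  p_m = p_m, ...)
}

# Independent eigen oracle: dense eigendecomposition from base R.
eigen_radius <- function(C) max(Mod(eigen(as.matrix(C))$values))
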