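# Small in-code fixtures: a noise-free (or lightly noisy) mixture with known
# S and C, sized for unit tests.

make_toy_mixture <- function(n_genes = 20, n_samples = 15, n_types = 3,
                             noise_sd = 0, seed = 42) {
  set.seed(seed)
  S <- matrix(rlnorm(n_genes * n_types, 3, 0.8), n_genes, n_types,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              LETTERS[seq_len(n_types)]))
  C <- rodeo::simulate_proportions(
    setNames(rep(1 / n_types, n_types), LETTERS[seq_len(n_types)]),
    n_samples, concentration = 20, seed = seed)
  E <- S %*% C
  if (noise_sd > 0) E <- pmax(E + matrix(rnorm(length(E), 0, noise_sd),
                                         nrow(E)), 0)
  list(S = S, C = C, E = rodeo::bulk_matrix(E))
}

# A design with clear composition variation, for single-gene regression tests.
make_design <- function(n = 30, p = 3, seed = 7) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0.1, 1), n, p,
              dimnames = list(NULL, paste0("t", seq_len(p))))
  X
}
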