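# Shared helpers: small random matrices and network collections built in
# code at test time.

rand_feature_matrix <- function(n = 10, p = 5, seed = 1, prefix = "f",
                                modality = "a") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("%s%02d", prefix, seq_len(p))))
  feature_matrix(m, modality)
}

rand_nets <- function(n_samples = 6, n_nodes = 5, seed = 1, scaled = TRUE) {
  set.seed(seed)
  edges <- all_edges(sprintf("g%02d", seq_len(n_nodes)))
  w <- matrix(runif(nrow(edges) * n_samples), nrow(edges), n_samples,
              dimnames = list(NULL, sprintf("s%02d", seq_len(n_samples))))
  ppnfuse:::new_individual_nets(edges, w, "node_product", scaled = scaled)
}

# Mean-type aggregate: the average over samples of the per-sample outer
# product; LIONESS must reconstruct each sample's own outer product exactly.
mean_product_aggregate <- function(m) {
  a <- crossprod(m) / nrow(m)
  diag(a) <- 0
  a
}

tiny_dataset <- function(seed = 1, n_train = 30, n_test = 12, p = 20,
                         mean_shift = 1, rho = c(0.7, 0)) {
  simulate_dataset(sim_spec(n_train = n_train, n_test = n_test, p_a = p,
                            p_b = p, mean_shift = mean_shift, rho = rho,
                            seed = seed))
}
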