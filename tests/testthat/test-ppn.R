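test_that("affinity PPN matches a step-by-step oracle on an 8-sample toy", {
  m <- rand_feature_matrix(8, 4, seed = 21)
  ppn <- affinity_ppn(m, K = 3, sigma = 0.5)
  expect_lt(max(abs(ppn$train - affinity_oracle(m, 3, 0.5))), 1e-10)
  # identical samples share the maximal affinity of their row
  m2 <- m; m2[2, ] <- m2[1, ]
  ppn2 <- affinity_ppn(feature_matrix(m2), K = 3, sigma = 0.5)
  off <- ppn2$train[1, -1]
  expect_equal(unname(which.max(off)), 1L)  # sample 2 is sample 1's closest
  # permutation equivariance
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  ppn_p <- affinity_ppn(feature_matrix(m[perm, ]), K = 3, sigma = 0.5)
  expect_equal(ppn_p$train[rownames(m), rownames(m)], ppn$train,
               tolerance = 1e-12)
  expect_error(affinity_ppn(m, K = 8), "smaller")
})

test_that("rectangular affinity reproduces a train row for an embedded sample", {
  m <- rand_feature_matrix(9, 4, seed = 22)
  ppn <- affinity_ppn(m, m_test = m[4, , drop = FALSE], K = 3, sigma = 0.5)
  expect_equal(unname(ppn$test[1, ]), unname(ppn$train[4, ]),
               tolerance = 1e-10)
  expect_equal(unname(ppn$self_test[1]), unname(ppn$train[4, 4]),
               tolerance = 1e-10)
})

test_that("gaussian PPN follows its closed form", {
  m <- rand_feature_matrix(6, 3, seed = 23)
  sg <- 2
  ppn <- gaussian_ppn(m, sigma = sg)
  expect_equal(unname(diag(ppn$train)), rep(1, 6))
  d <- as.matrix(dist(m))
  expect_lt(max(abs(ppn$train - exp(-d^2 / sg^2))), 1e-12)
  # ||v_x - v_y|| = sigma gives exp(-1)
  m2 <- matrix(c(0, 0, sg, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("x", "y"), c("f1", "f2")))
  expect_equal(gaussian_ppn(feature_matrix(m2), sigma = sg)$train["x", "y"],
               exp(-1))
  expect_error(gaussian_ppn(m, sigma = 0), "positive")
})

test_that("spearman PPN equals brute-force rank correlation", {
  m <- rand_feature_matrix(5, 6, seed = 24)
  ppn <- spearman_ppn(m)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(ppn$train[i, j], cor(rank(m[i, ]), rank(m[j, ])),
                 tolerance = 1e-12)
  # reversed ranks give -1; monotone transforms leave the PPN unchanged
  m2 <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  colnames(m2) <- paste0("f", 1:4)
  expect_equal(spearman_ppn(feature_matrix(m2))$train["a", "b"], -1)
  m3 <- m; m3[1, ] <- exp(m3[1, ])  # strictly monotone in sample 1
  expect_equal(spearman_ppn(feature_matrix(m3))$train, ppn$train,
               tolerance = 1e-12)
  mc <- m; mc[2, ] <- 0.3
  expect_error(spearman_ppn(feature_matrix(mc)), "s02")
})

test_that("edge difference distance is the Frobenius norm of adjacency difference", {
  # single edge, weights 0.2 vs 0.6
  expect_equal(edge_difference_distance(0.2, 0.6), sqrt(2 * 0.16))
  nets <- rand_nets(2, 5, seed = 25)
  a <- nets$weights[, 1]; b <- nets$weights[, 2]
  expect_equal(edge_difference_distance(a, a), 0)
  # dense-matrix oracle
  nodes <- sprintf("g%02d", 1:5)
  to_adj <- function(w) {
    adj <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
    for (e in seq_len(nrow(nets$edges))) {
      adj[nets$edges$a[e], nets$edges$b[e]] <- w[e]
      adj[nets$edges$b[e], nets$edges$a[e]] <- w[e]
    }
    adj
  }
  expect_equal(edge_difference_distance(a, b),
               norm(to_adj(a) - to_adj(b), "F"), tolerance = 1e-12)
  # metric axioms on random triples
  set.seed(26)
  for (k in 1:25) {
    w3 <- matrix(runif(3 * nrow(nets$edges)), ncol = 3)
    dab <- edge_difference_distance(w3[, 1], w3[, 2])
    dbc <- edge_difference_distance(w3[, 2], w3[, 3])
    dac <- edge_difference_distance(w3[, 1], w3[, 3])
    expect_gte(dab, 0)
    expect_equal(dab, edge_difference_distance(w3[, 2], w3[, 1]))
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("edge PPN is the affinity transform of the distance matrix", {
  nets <- rand_nets(6, 5, seed = 27)
  ppn <- edge_ppn(nets, K = 3, sigma = 0.5)
  n <- ncol(nets$weights)
  d <- matrix(0, n, n, dimnames = list(colnames(nets$weights),
                                       colnames(nets$weights)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- edge_difference_distance(nets$weights[, i], nets$weights[, j])
  oracle <- ppnfuse:::affinity_from_dist(d, K = 3, sigma = 0.5)$train
  expect_lt(max(abs(ppn$train - oracle)), 1e-12)
  # identical networks: constant affinity matrix
  same <- nets; same$weights[] <- same$weights[, 1]
  ppn_same <- edge_ppn(same, K = 3, sigma = 0.5)
  expect_lt(diff(range(ppn_same$train)), 1e-12)
  # permutation equivariance
  perm <- c(4, 1, 6, 2, 5, 3)
  netp <- ppnfuse:::new_individual_nets(nets$edges, nets$weights[, perm],
                                        "node_product", scaled = TRUE)
  ppn_p <- edge_ppn(netp, K = 3, sigma = 0.5)
  ids <- colnames(nets$weights)
  expect_equal(ppn_p$train[ids, ids], ppn$train, tolerance = 1e-12)
})

test_that("PPN normalization yields unit diagonal and is idempotent", {
  w <- matrix(c(4, 2, 2, 9), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  norm1 <- normalize_ppn(w)
  expect_equal(unname(diag(norm1)), c(1, 1))
  expect_equal(norm1["a", "b"], 2 / sqrt(36))
  # correlation-like PPN is a fixed point
  m <- rand_feature_matrix(6, 5, seed = 28)
  sp <- spearman_ppn(m)
  expect_equal(normalize_ppn(sp)$train, sp$train, tolerance = 1e-12)
  # symmetry and sign pattern preserved
  set.seed(29)
  x <- matrix(rnorm(25), 5, 5); x <- x %*% t(x) + diag(5)
  dimnames(x) <- list(paste0("s", 1:5), paste0("s", 1:5))
  nx <- normalize_ppn(x)
  expect_equal(nx, t(nx))
  expect_identical(sign(nx), sign(x))
  bad <- x; bad[1, 1] <- -1
  expect_error(normalize_ppn(bad), "self-similarity")
})

test_that("rectangular normalization uses each sample's own self-similarity", {
  m <- rand_feature_matrix(8, 4, seed = 30)
  te <- rand_feature_matrix(3, 4, seed = 31)
  rownames(te) <- paste0("t", 1:3)
  ppn <- normalize_ppn(affinity_ppn(m, te, K = 3, sigma = 0.5))
  raw <- affinity_ppn(m, te, K = 3, sigma = 0.5)
  manual <- raw$test / outer(sqrt(raw$self_test), sqrt(diag(raw$train)))
  expect_equal(ppn$test, manual, tolerance = 1e-12)
  expect_equal(unname(ppn$self_test), rep(1, 3))
})

test_that("combining node and edge PPNs averages elementwise", {
  m <- rand_feature_matrix(6, 5, seed = 32)
  p1 <- normalize_ppn(spearman_ppn(m))
  p2 <- normalize_ppn(gaussian_ppn(m, sigma = 5))
  comb <- combine_node_edge(p1, p2)
  expect_equal(comb$train, (p1$train + p2$train) / 2)
  expect_identical(comb$kind, "combined")
  # idempotence on identical inputs
  expect_equal(combine_node_edge(p1, p1)$train, p1$train)
  # ID mismatch is an error
  m2 <- rand_feature_matrix(6, 5, seed = 33)
  rownames(m2) <- paste0("x", 1:6)
  p3 <- normalize_ppn(spearman_ppn(feature_matrix(m2)))
  expect_error(combine_node_edge(p1, p3), "differ")
  expect_error(combine_node_edge(spearman_ppn(m), p2), "normalize_ppn")
})
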