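sim_edge_matrix <- function(n_edges = 30, n1 = 8, n2 = 8, delta = 0,
                            n_signal = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_edges * (n1 + n2), sd = runif(n_edges, 0.5, 2)),
              n_edges, n1 + n2)
  if (n_signal > 0)
    m[seq_len(n_signal), seq_len(n1)] <-
      m[seq_len(n_signal), seq_len(n1)] + delta
  rownames(m) <- paste0("g", seq_len(n_edges), "|h", seq_len(n_edges))
  colnames(m) <- sprintf("s%02d", seq_len(n1 + n2))
  groups <- setNames(rep(c("grp1", "grp2"), c(n1, n2)), colnames(m))
  list(m = m, groups = groups)
}

test_that("edge matrices are edges x samples with ID-sorted columns", {
  nets <- rand_nets(3, 4, seed = 71)
  colnames(nets$weights) <- c("s3", "s1", "s2")
  em <- edge_matrix(nets)
  expect_equal(dim(em), c(6L, 3L))
  expect_identical(colnames(em), c("s1", "s2", "s3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(nets, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 6)
})

test_that("per-edge coefficients and variances match an lm oracle", {
  fx <- sim_edge_matrix(seed = 72)
  st <- moderated_t_stats(fx$m, fx$groups)
  d0 <- attr(st, "df_prior"); s02 <- attr(st, "s2_prior")
  for (e in c(1, 7, 30)) {
    id <- rownames(fx$m)[e]
    fit <- lm(fx$m[e, ] ~ factor(fx$groups, levels = c("grp2", "grp1")))
    row <- st[st$id == id, ]
    expect_equal(row$coef, unname(coef(fit)[2]), tolerance = 1e-10)
    s2_lm <- sum(residuals(fit)^2) / fit$df.residual
    expect_equal(unname(attr(st, "s2")[id]), s2_lm, tolerance = 1e-10)
    # moderated t rebuilt from the squeezed variance
    s2_post <- (d0 * s02 + fit$df.residual * s2_lm) / (d0 + fit$df.residual)
    se <- sqrt(s2_post) * sqrt(1 / 8 + 1 / 8)
    expect_equal(row$t, unname(coef(fit)[2]) / se, tolerance = 1e-8)
  }
})

test_that("the variance prior matches a direct solve of the moment equations", {
  fx <- sim_edge_matrix(seed = 73)
  st <- moderated_t_stats(fx$m, fx$groups)
  d <- attr(st, "df_residual")
  s2 <- attr(st, "s2")
  # method of moments on log s^2 (Smyth 2004): solve for d0 from the
  # excess variance of log s^2 over trigamma(d/2), then s0^2
  z <- log(s2)
  e_z <- z - digamma(d / 2) + log(d / 2)
  var_excess <- var(e_z) - trigamma(d / 2)
  if (var_excess > 0) {
    # invert trigamma numerically: trigamma(d0/2) = var_excess
    d0_direct <- 2 * uniroot(function(x) trigamma(x) - var_excess,
                             c(1e-3, 1e3), tol = 1e-12)$root
    s02_direct <- exp(mean(e_z) + digamma(d0_direct / 2) -
                        log(d0_direct / 2))
    expect_equal(attr(st, "df_prior"), d0_direct, tolerance = 1e-3)
    expect_equal(attr(st, "s2_prior"), s02_direct, tolerance = 1e-3)
  } else {
    expect_true(is.infinite(attr(st, "df_prior")))
  }
})

test_that("moderated statistics agree with the limma pipeline", {
  fx <- sim_edge_matrix(delta = 1.5, n_signal = 5, seed = 74)
  st <- moderated_t_stats(fx$m, fx$groups)
  design <- model.matrix(~ 0 + factor(fx$groups))
  colnames(design) <- levels(factor(fx$groups))
  fit <- limma::lmFit(fx$m, design)
  fit <- limma::contrasts.fit(
    fit, limma::makeContrasts(grp1 - grp2, levels = design))
  fit <- limma::eBayes(fit)
  tab <- limma::topTable(fit, number = Inf, sort.by = "none")
  ord <- match(st$id, rownames(tab))
  expect_equal(st$coef, tab$logFC[ord], tolerance = 1e-8)
  expect_equal(st$t, tab$t[ord], tolerance = 1e-8)
  expect_equal(st$p_value, tab$P.Value[ord], tolerance = 1e-8)
  expect_equal(attr(st, "df_prior"), fit$df.prior, tolerance = 1e-6)
})

test_that("zero prior df reduces to the ordinary two-sample t", {
  fx <- sim_edge_matrix(seed = 75)
  st0 <- moderated_t_stats(fx$m, fx$groups, prior_df = 0)
  for (e in c(2, 15)) {
    id <- rownames(fx$m)[e]
    tt <- t.test(fx$m[e, fx$groups == "grp1"], fx$m[e, fx$groups == "grp2"],
                 var.equal = TRUE)
    expect_equal(st0$t[st0$id == id], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(st0$p_value[st0$id == id], tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical residual variances are a fixed point of the squeeze", {
  set.seed(76)
  base <- rnorm(16)
  m <- t(vapply(1:20, function(i) base + i, numeric(16)))  # shifted copies
  rownames(m) <- paste0("a", 1:20, "|b", 1:20)
  colnames(m) <- sprintf("s%02d", 1:16)
  groups <- setNames(rep(c("g1", "g2"), each = 8), colnames(m))
  st <- moderated_t_stats(m, groups)
  s2 <- attr(st, "s2")
  expect_lt(diff(range(s2)), 1e-12)
  # posterior variance equals the common s2 for every edge
  d <- attr(st, "df_residual")
  se <- sqrt(1 / 8 + 1 / 8)
  expect_equal(st$t, st$coef / (sqrt(s2[1]) * se), tolerance = 1e-6)
})

test_that("adjusted p-values are BH-monotone and bound raw p-values", {
  fx <- sim_edge_matrix(delta = 2, n_signal = 6, seed = 77)
  st <- moderated_t_stats(fx$m, fx$groups)
  expect_true(all(st$adj_p >= st$p_value - 1e-15))
  ord <- order(st$p_value)
  cm <- cummax(st$adj_p[ord])
  expect_equal(st$adj_p[ord], cm, tolerance = 1e-12)
})

test_that("null labels give uniform moderated-t p-values", {
  # variances drawn from the conjugate prior (scaled inverse chi-square),
  # under which the moderated t is exactly t-distributed
  set.seed(78)
  d0 <- 4; s0 <- 1; n1 <- n2 <- 15
  sigma2 <- d0 * s0^2 / rchisq(300, df = d0)
  m <- t(vapply(sigma2, function(v) rnorm(n1 + n2, sd = sqrt(v)),
                numeric(n1 + n2)))
  rownames(m) <- paste0("a", 1:300, "|b", 1:300)
  colnames(m) <- sprintf("s%02d", 1:(n1 + n2))
  groups <- setNames(rep(c("g1", "g2"), each = 15), colnames(m))
  st <- moderated_t_stats(m, groups)
  ks <- suppressWarnings(ks.test(st$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("top-edge networks annotate direction, width and node masking", {
  fx <- sim_edge_matrix(delta = 3, n_signal = 10, seed = 79)
  st <- moderated_t_stats(fx$m, fx$groups)
  gene_t <- setNames(c(2, -1.0, 1.7), c("g1", "h1", "g2"))
  net <- top_edges_network(st, n = 10, gene_stats = gene_t)
  expect_equal(nrow(net$edges), 10)
  # planted edges dominate the top 10
  expect_gte(sum(paste0(net$edges$node_a, "|", net$edges$node_b) %in%
                   rownames(fx$m)[1:10]), 8)
  expect_identical(net$nodes$color[net$nodes$gene == "h1"], "white")
  expect_identical(net$nodes$color[net$nodes$gene == "g1"], "group1_higher")
  expect_equal(net$edges$width, abs(net$edges$coef))
  expect_error(top_edges_network(st, n = 1000), "top")
  path <- withr::local_tempfile()
  write_network(net, path)
  expect_true(file.exists(paste0(path, ".graphml")))
})

test_that("largest component matches a brute-force union-find", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = c("a", "b", "d"), b = c("b", "c", "e")),
    directed = FALSE)
  expect_identical(largest_component(g), c("a", "b", "c"))
  full <- igraph::make_full_graph(4)
  igraph::V(full)$name <- c("w", "x", "y", "z")
  expect_identical(largest_component(full), c("w", "x", "y", "z"))
  # random graph vs union-find oracle
  set.seed(80)
  for (rep in 1:5) {
    nodes <- paste0("n", 1:12)
    a <- sample(nodes, 10, replace = TRUE)
    b <- sample(nodes, 10, replace = TRUE)
    keep <- a != b
    eg <- unique(data.frame(a = pmin(a[keep], b[keep]),
                            b = pmax(a[keep], b[keep])))
    g2 <- igraph::graph_from_data_frame(eg, directed = FALSE)
    parent <- seq_along(nodes)
    find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in seq_len(nrow(eg))) {
      ra <- find_root(match(eg$a[e], nodes))
      rb <- find_root(match(eg$b[e], nodes))
      if (ra != rb) parent[ra] <- rb
    }
    present <- match(unique(c(eg$a, eg$b)), nodes)
    comp <- split(nodes[present], vapply(present, find_root, 0L))
    if (sum(lengths(comp) == max(lengths(comp))) == 1) {
      best <- comp[[which.max(lengths(comp))]]
      expect_setequal(largest_component(g2), best)
    }
  }
})

test_that("enrichment scores equal the brute-force running sum", {
  set.seed(81)
  ranked <- setNames(sort(rnorm(20, sd = 2), decreasing = TRUE),
                     paste0("gene", 1:20))
  sets <- list(up = paste0("gene", 1:5),
               down = paste0("gene", 16:20),
               spread = paste0("gene", c(2, 7, 12, 17)))
  res <- gsea_preranked(ranked, sets, min_size = 3, n_perm = 500, seed = 1)
  for (nm in names(sets)) {
    expect_equal(res$es[res$pathway == nm],
                 unname(gsea_es_oracle(ranked, sets[[nm]])),
                 tolerance = 1e-12)
  }
  # single top-ranked gene: the running sum jumps straight to its maximum
  solo <- gsea_preranked(ranked, list(top = names(ranked)[1]),
                         min_size = 1, n_perm = 500, seed = 1)
  expect_equal(solo$es, unname(gsea_es_oracle(ranked, names(ranked)[1])))
  expect_equal(solo$es, 1)
})

test_that("small sets are filtered and permutation p-values are seed-stable", {
  set.seed(82)
  ranked <- setNames(rnorm(30), paste0("g", 1:30))
  sets <- list(big = paste0("g", 1:12), small = paste0("g", 1:3))
  res <- gsea_preranked(ranked, sets, min_size = 10, n_perm = 500, seed = 1)
  expect_false("small" %in% res$pathway)
  r1 <- gsea_preranked(ranked, sets, min_size = 10, n_perm = 500, seed = 1)
  expect_identical(res$p_value, r1$p_value)
  r2 <- gsea_preranked(ranked, sets, min_size = 10, n_perm = 500, seed = 2)
  # Monte-Carlo agreement across seeds: 3 x SE at 500 permutations
  p <- res$p_value[res$pathway == "big"]
  se <- sqrt(p * (1 - p) / 500)
  expect_lt(abs(p - r2$p_value[r2$pathway == "big"]), 3 * se + 2 / 500)
  expect_error(gsea_preranked(setNames(numeric(0), character(0)), sets),
               "empty")
  expect_error(gsea_preranked(setNames(c(1, 2), c("a", "a")), sets),
               "duplicate")
})

test_that("reversing the ranking negates enrichment scores", {
  set.seed(83)
  ranked <- setNames(rnorm(25), paste0("g", 1:25))
  sets <- list(s1 = paste0("g", 1:8), s2 = paste0("g", 10:20))
  a <- gsea_preranked(ranked, sets, min_size = 5, n_perm = 200, seed = 1)
  b <- gsea_preranked(-ranked, sets, min_size = 5, n_perm = 200, seed = 1)
  ord <- match(a$pathway, b$pathway)
  expect_equal(a$es, -b$es[ord], tolerance = 1e-10)
})
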