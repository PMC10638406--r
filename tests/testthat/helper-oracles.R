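# Independent oracle for the scaled exponential similarity kernel, written
# as an explicit double loop from the construction's definition.
affinity_oracle <- function(m, K, sigma) {
  d <- as.matrix(dist(m))
  n <- nrow(d)
  mu <- numeric(n)
  for (i in seq_len(n))
    mu[i] <- mean(sort(d[i, -i])[1:K]) + .Machine$double.eps
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    eps <- (mu[i] + mu[j] + d[i, j]) / 3 + .Machine$double.eps
    w[i, j] <- dnorm(d[i, j], 0, sigma * eps)
  }
  dimnames(w) <- dimnames(d)
  (w + t(w)) / 2
}


# Independent step-by-step SNF reference: loops coded directly from the
# cross-diffusion update equations.
snf_oracle <- function(ws, K, iterations) {
  n <- nrow(ws[[1]])
  full_kernel <- function(w) {
    p <- matrix(0, n, n)
    for (i in 1:n) {
      rs <- sum(w[i, ]) - w[i, i]
      for (j in 1:n) if (j != i) p[i, j] <- w[i, j] / (2 * rs)
      p[i, i] <- 0.5
    }
    p
  }
  knn_kernel <- function(w) {
    s <- matrix(0, n, n)
    for (i in 1:n) {
      others <- setdiff(1:n, i)
      nb <- others[order(w[i, others], decreasing = TRUE)][1:K]
      for (j in nb) s[i, j] <- w[i, j] / sum(w[i, nb])
    }
    s
  }
  ws <- lapply(ws, function(w) (w + t(w)) / 2)
  ps <- lapply(ws, full_kernel)
  ss <- lapply(ws, knn_kernel)
  fused_prev <- Reduce(`+`, ps) / length(ps)
  for (it in seq_len(iterations)) {
    ps_new <- ps
    for (v in seq_along(ps)) {
      others <- Reduce(`+`, ps[-v]) / (length(ps) - 1)
      p <- ss[[v]] %*% others %*% t(ss[[v]])
      ps_new[[v]] <- full_kernel((p + t(p)) / 2)
    }
    ps <- ps_new
    fused <- Reduce(`+`, ps) / length(ps)
    if (max(abs(fused - fused_prev)) < 1e-8) break
    fused_prev <- fused
  }
  fused <- Reduce(`+`, ps) / length(ps)
  (fused + t(fused)) / 2
}


gsea_es_oracle <- function(ranked, set) {
  ord <- order(ranked, decreasing = TRUE)
  stats <- ranked[ord]
  hit <- names(stats) %in% set
  nr <- sum(abs(stats[hit]))
  n_miss <- sum(!hit)
  p_hit <- cumsum(ifelse(hit, abs(stats) / nr, 0))
  p_miss <- cumsum(ifelse(hit, 0, 1 / n_miss))
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

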