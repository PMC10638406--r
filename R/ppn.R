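#' Person-to-Person Network container
#'
#' A square train-by-train similarity matrix, optionally paired with a
#' rectangular test-by-train block and the test samples' self-similarities
#' (needed for cosine normalization of the rectangular block).
#'
#' @param train Square numeric matrix with sample-ID dimnames.
#' @param test Optional rectangular test-by-train matrix.
#' @param self_test Optional named vector of test self-similarities.
#' @param kind One of `"node"`, `"edge"`, `"combined"`, `"fused"`.
#' @param normalized Whether cosine normalization has been applied.
#' @return An object of class `"ppn"`.
#' @export
new_ppn <- function(train, test = NULL, self_test = NULL, kind = "node",
                    normalized = FALSE) {
  check_finite(train, "PPN")
  if (nrow(train) != ncol(train) ||
      !isTRUE(all.equal(rownames(train), colnames(train))))
    stop2("train PPN must be square with matching sample IDs")
  if (max(abs(train - t(train))) > 1e-10)
    stop2("train PPN must be symmetric")
  train <- (train + t(train)) / 2
  if (!is.null(test)) {
    check_finite(test, "test PPN")
    if (!identical(colnames(test), colnames(train)))
      stop2("test PPN columns must match train sample IDs")
    if (is.null(self_test))
      stop2("rectangular PPN requires test self-similarities")
    self_test <- self_test[rownames(test)]
    if (any(is.na(self_test))) stop2("self_test must cover all test samples")
  }
  structure(list(train = train, test = test, self_test = self_test,
                 kind = kind, normalized = normalized), class = "ppn")
}

#' @export
print.ppn <- function(x, ...) {
  cat("PPN (", x$kind, if (x$normalized) ", normalized" else "", "): ",
      nrow(x$train), " train samples",
      if (!is.null(x$test)) paste0(", ", nrow(x$test), " test samples"),
      "\n", sep = "")
  invisible(x)
}

# Cross Euclidean distances via stats::dist on the stacked matrix: the
# pairwise sum of squared differences is exact for identical rows (the
# expanded-square form is not).
euclidean_cross <- function(a, b) {
  d <- as.matrix(stats::dist(rbind(a, b)))
  out <- d[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b)), drop = FALSE]
  dimnames(out) <- list(rownames(a), rownames(b))
  out
}

# Scaled exponential similarity kernel on a distance matrix (the SNF-style
# affinity construction): per-sample bandwidth from the mean distance to
# the K nearest neighbours, density evaluated as dnorm(d, 0, sigma * eps)
# with eps = (mu_x + mu_y + d) / 3. Small sigma sharpens the kernel
# towards its diagonal; the node-level default follows the workflow's
# empirical 0.05 while the edge-distance conversion keeps the affinity
# construction's conventional 0.5.
affinity_from_dist <- function(d_train, d_test = NULL, K = 20, sigma = 0.05) {
  n <- nrow(d_train)
  if (K >= n) stop2("K (", K, ") must be smaller than the number of ",
                    "training samples (", n, ")")
  knn_mean <- function(dists) mean(sort(dists)[seq_len(K)]) +
    .Machine$double.eps
  mu <- vapply(seq_len(n), function(i) knn_mean(d_train[i, -i]), numeric(1))
  eps_tr <- outer(mu, mu, `+`) / 3 + d_train / 3 + .Machine$double.eps
  w_tr <- stats::dnorm(d_train, 0, sigma * eps_tr)
  w_tr <- (w_tr + t(w_tr)) / 2
  dimnames(w_tr) <- dimnames(d_train)
  out <- list(train = w_tr)
  if (!is.null(d_test)) {
    mu_te <- apply(d_test, 1, function(r) knn_mean(r[r > 0]))
    eps_te <- (outer(mu_te, mu, `+`) + d_test) / 3 + .Machine$double.eps
    w_te <- stats::dnorm(d_test, 0, sigma * eps_te)
    dimnames(w_te) <- dimnames(d_test)
    out$test <- w_te
    out$self_test <- stats::setNames(
      stats::dnorm(0, 0, sigma * (2 * mu_te / 3 + .Machine$double.eps)),
      rownames(d_test))
  }
  out
}

#' Affinity-kernel node-level PPN
#'
#' Euclidean distances between samples' feature vectors are converted into
#' similarities with the scaled exponential similarity kernel: each
#' sample's bandwidth comes from the mean distance to its `K` nearest
#' neighbours, and the affinity of samples x and y is the normal density of
#' their distance at scale `sigma * eps(x, y)` where
#' `eps = (mu_x + mu_y + d(x, y)) / 3`.
#'
#' @param m Training feature matrix (samples x features).
#' @param m_test Optional held-out feature matrix over the same features.
#' @param K Neighbourhood size (default 20).
#' @param sigma Kernel hyperparameter (default 0.05).
#' @return A [new_ppn()] of kind `"node"`.
#' @export
affinity_ppn <- function(m, m_test = NULL, K = 20, sigma = 0.05) {
  d_tr <- as.matrix(stats::dist(m))
  d_te <- if (!is.null(m_test))
    euclidean_cross(m_test[, colnames(m), drop = FALSE], m)
  aff <- affinity_from_dist(d_tr, d_te, K = K, sigma = sigma)
  new_ppn(aff$train, aff$test, aff$self_test, kind = "node")
}

#' Gaussian-kernel node-level PPN
#'
#' `k(x, y) = exp(-||v_x - v_y||^2 / sigma^2)` on the samples' feature
#' vectors; the diagonal is exactly 1.
#'
#' @inheritParams affinity_ppn
#' @param sigma Kernel bandwidth (default 1000).
#' @return A [new_ppn()] of kind `"node"`.
#' @export
gaussian_ppn <- function(m, m_test = NULL, sigma = 1000) {
  if (sigma <= 0) stop2("sigma must be positive")
  d_tr <- as.matrix(stats::dist(m))
  w_tr <- exp(-d_tr^2 / sigma^2)
  test <- self_test <- NULL
  if (!is.null(m_test)) {
    d_te <- euclidean_cross(m_test[, colnames(m), drop = FALSE], m)
    test <- exp(-d_te^2 / sigma^2)
    self_test <- stats::setNames(rep(1, nrow(m_test)), rownames(m_test))
  }
  new_ppn(w_tr, test, self_test, kind = "node")
}

#' Spearman-correlation node-level PPN
#'
#' Entry (x, y) is the Spearman rank correlation between the two samples'
#' feature vectors (average ranks for ties). Entries can be negative.
#'
#' @inheritParams affinity_ppn
#' @return A [new_ppn()] of kind `"node"`.
#' @export
spearman_ppn <- function(m, m_test = NULL) {
  if (ncol(m) < 3) stop2("Spearman PPN needs at least 3 features")
  check_nonconstant <- function(x) {
    const <- apply(x, 1, function(r) max(r) == min(r))
    if (any(const))
      stop2("constant feature vector for sample(s): ",
            paste(utils::head(rownames(x)[const], 5), collapse = ", "))
  }
  check_nonconstant(m)
  w_tr <- stats::cor(t(m), method = "spearman")
  test <- self_test <- NULL
  if (!is.null(m_test)) {
    m_test <- m_test[, colnames(m), drop = FALSE]
    check_nonconstant(m_test)
    test <- stats::cor(t(m_test), t(m), method = "spearman")
    self_test <- stats::setNames(rep(1, nrow(m_test)), rownames(m_test))
  }
  new_ppn(w_tr, test, self_test, kind = "node")
}

#' Edge-difference distance between two individual networks
#'
#' Frobenius norm of the difference of the two full symmetric adjacency
#' matrices; each undirected edge contributes twice, so the distance is
#' `sqrt(2 * sum((w_a - w_b)^2))` over the shared edge set.
#'
#' @param a,b Single-sample `individual_nets` objects (or bare numeric
#'   weight vectors over the same edge set).
#' @return Nonnegative scalar; zero iff the weights are identical.
#' @export
edge_difference_distance <- function(a, b) {
  wa <- if (inherits(a, "individual_nets")) a$weights[, 1] else a
  wb <- if (inherits(b, "individual_nets")) b$weights[, 1] else b
  if (inherits(a, "individual_nets") && inherits(b, "individual_nets") &&
      !identical(edge_ids(a$edges), edge_ids(b$edges)))
    stop2("networks are defined over different edge sets")
  if (length(wa) != length(wb)) stop2("edge weight vectors differ in length")
  sqrt(2 * sum((wa - wb)^2))
}

# All pairwise edge-difference distances; columns of `weights` are samples.
edge_distance_matrix <- function(w_a, w_b = NULL) {
  if (is.null(w_b)) as.matrix(stats::dist(t(w_a))) * sqrt(2)
  else euclidean_cross(t(w_b), t(w_a)) * sqrt(2)
}

#' Edge-level PPN from individual networks
#'
#' Pairwise edge-difference distances between individual networks are
#' turned into similarities, by default with the same scaled exponential
#' affinity kernel as [affinity_ppn()].
#'
#' @param train_nets Scaled `individual_nets` collection for the training
#'   samples.
#' @param test_nets Either a scaled `individual_nets` collection (Node
#'   Product) or the per-sample panel list from [lioness_test_networks()]
#'   after global rescaling; optional.
#' @param K,sigma Affinity kernel parameters.
#' @param similarity `"affinity"` (default), `"gaussian"` (with bandwidth
#'   `sigma`), or `"neg_distance"`.
#' @return A [new_ppn()] of kind `"edge"`.
#' @export
edge_ppn <- function(train_nets, test_nets = NULL, K = 20, sigma = 0.5,
                     similarity = c("affinity", "gaussian", "neg_distance")) {
  similarity <- match.arg(similarity)
  stopifnot(inherits(train_nets, "individual_nets"))
  d_tr <- edge_distance_matrix(train_nets$weights)
  d_te <- NULL
  if (!is.null(test_nets)) {
    if (inherits(test_nets, "individual_nets")) {
      if (!identical(edge_ids(test_nets$edges), edge_ids(train_nets$edges)))
        stop2("train and test networks use different edge sets")
      d_te <- edge_distance_matrix(train_nets$weights, test_nets$weights)
    } else {
      # one-at-a-time LIONESS panels: distances taken against the panel's
      # refreshed training networks (one row per panel, computed directly)
      d_te <- t(vapply(test_nets, function(panel) {
        diff <- panel$train$weights - panel$test$weights[, 1]
        sqrt(2 * colSums(diff^2))
      }, numeric(ncol(train_nets$weights))))
      rownames(d_te) <- names(test_nets)
      colnames(d_te) <- colnames(train_nets$weights)
    }
  }
  if (similarity == "affinity") {
    aff <- affinity_from_dist(d_tr, d_te, K = K, sigma = sigma)
    return(new_ppn(aff$train, aff$test, aff$self_test, kind = "edge"))
  }
  if (similarity == "gaussian") {
    w_tr <- exp(-d_tr^2 / sigma^2)
    test <- if (!is.null(d_te)) exp(-d_te^2 / sigma^2)
    self <- if (!is.null(d_te))
      stats::setNames(rep(1, nrow(d_te)), rownames(d_te))
    return(new_ppn(w_tr, test, self, kind = "edge"))
  }
  self <- if (!is.null(d_te))
    stats::setNames(rep(0, nrow(d_te)), rownames(d_te))
  new_ppn(-d_tr, if (!is.null(d_te)) -d_te, self, kind = "edge")
}

#' Average node-level and edge-level PPNs
#'
#' Elementwise mean of two normalized PPNs over identical samples.
#'
#' @param ppn_n,ppn_e Normalized [new_ppn()] objects with identical IDs.
#' @return A [new_ppn()] of kind `"combined"`.
#' @export
combine_node_edge <- function(ppn_n, ppn_e) {
  stopifnot(inherits(ppn_n, "ppn"), inherits(ppn_e, "ppn"))
  if (!ppn_n$normalized || !ppn_e$normalized)
    stop2("combine PPNs after normalize_ppn so scales are comparable")
  if (!identical(dimnames(ppn_n$train), dimnames(ppn_e$train)))
    stop2("train sample IDs differ between the two PPNs")
  test <- self <- NULL
  if (!is.null(ppn_n$test) || !is.null(ppn_e$test)) {
    if (is.null(ppn_n$test) || is.null(ppn_e$test) ||
        !identical(dimnames(ppn_n$test), dimnames(ppn_e$test)))
      stop2("test sample IDs differ between the two PPNs")
    test <- (ppn_n$test + ppn_e$test) / 2
    self <- (ppn_n$self_test + ppn_e$self_test) / 2
  }
  new_ppn((ppn_n$train + ppn_e$train) / 2, test, self, kind = "combined",
          normalized = TRUE)
}

#' Cosine-normalize a PPN
#'
#' `PPN(x, y) / sqrt(PPN(x, x) * PPN(y, y))`: the square block gets a unit
#' diagonal; rectangular test rows are scaled by each test sample's own
#' self-similarity under the same similarity function.
#'
#' @param ppn A [new_ppn()] object, or a bare square similarity matrix.
#' @return Normalized object of the same shape.
#' @export
normalize_ppn <- function(ppn) {
  if (is.matrix(ppn))
    return(normalize_ppn(new_ppn(ppn))$train)
  stopifnot(inherits(ppn, "ppn"))
  d <- diag(ppn$train)
  if (any(d <= 0))
    stop2("nonpositive self-similarity for sample(s): ",
          paste(utils::head(rownames(ppn$train)[d <= 0], 5), collapse = ", "))
  s <- sqrt(d)
  train <- ppn$train / tcrossprod(s)
  diag(train) <- 1
  test <- self <- ppn$self_test
  if (!is.null(ppn$test)) {
    if (any(ppn$self_test <= 0))
      stop2("nonpositive self-similarity for test sample(s): ",
            paste(utils::head(names(ppn$self_test)[ppn$self_test <= 0], 5),
                  collapse = ", "))
    test <- ppn$test / outer(sqrt(ppn$self_test), s)
    self <- stats::setNames(rep(1, length(ppn$self_test)),
                            names(ppn$self_test))
  }
  new_ppn(train, test, self, kind = ppn$kind, normalized = TRUE)
}
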