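#' Select the most variable features
#'
#' The `n_nodes` features with the largest sample standard deviation on the
#' training data; ties broken by lexicographic feature ID.
#'
#' @param m Training feature matrix.
#' @param n_nodes Number of features to keep.
#' @return Character vector of feature IDs, most variable first.
#' @export
select_top_nodes <- function(m, n_nodes) {
  if (n_nodes > ncol(m))
    stop2("n_nodes (", n_nodes, ") exceeds the number of features (",
          ncol(m), ")")
  if (n_nodes < 2) stop2("n_nodes must be at least 2")
  sds <- apply(m, 2, stats::sd)
  ids <- colnames(m)
  ids[order(-sds, ids)][seq_len(n_nodes)]
}

#' Condition-specific aggregate networks
#'
#' One adjacency per class over the selected nodes, built from that class's
#' training samples only. `"pearson"` (default) uses the class-wise
#' correlation network, which responds directly to co-expression
#' differences; `"mean_node_product"` averages the per-sample Node Product
#' adjacencies (min-max scaling fitted on the full training set).
#'
#' @param m Training feature matrix.
#' @param labels Named label vector covering the rows of `m`.
#' @param nodes Selected feature IDs.
#' @param method `"mean_node_product"` or `"pearson"`.
#' @return Named list (one adjacency matrix per class).
#' @export
condition_networks <- function(m, labels, nodes,
                               method = c("pearson", "mean_node_product")) {
  method <- match.arg(method)
  labels <- labels[rownames(m)]
  if (any(is.na(labels))) stop2("labels missing for some samples")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop2("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 3))
    stop2("class(es) with fewer than 3 samples: ",
          paste(names(counts)[counts < 3], collapse = ", "))
  m <- m[, nodes, drop = FALSE]
  if (method == "mean_node_product") {
    scaled <- min_max_scale_features(m)$values
    lapply(stats::setNames(classes, classes), function(cl) {
      x <- scaled[labels == cl, , drop = FALSE]
      adj <- crossprod(x) / nrow(x)
      diag(adj) <- 0
      adj
    })
  } else {
    lapply(stats::setNames(classes, classes), function(cl)
      pearson_adjacency(m[labels == cl, , drop = FALSE]))
  }
}

#' Select edges with the largest between-class difference
#'
#' Computes `D = |A_class1 - A_class2|` on the upper triangle of the two
#' condition-specific adjacencies and keeps edges whose difference strictly
#' exceeds the `t_edge` quantile of all upper-triangle values, so larger
#' thresholds keep fewer edges and the retained sets are nested.
#'
#' @param per_class List of exactly two adjacency matrices over the same
#'   node set (see [condition_networks()]).
#' @param t_edge Percentile threshold in (0, 1), e.g. 0.25, 0.5, 0.75.
#' @return An [edge_set()], ordered by decreasing difference.
#' @export
select_edges <- function(per_class, t_edge) {
  if (length(per_class) != 2)
    stop2("edge selection is defined for exactly two classes")
  a1 <- per_class[[1]]; a2 <- per_class[[2]]
  if (!identical(colnames(a1), colnames(a2)))
    stop2("condition networks are defined over different node sets")
  if (t_edge <= 0 || t_edge >= 1) stop2("t_edge must lie in (0, 1)")
  nodes <- colnames(a1)
  pairs <- upper_pairs(nodes)
  idx <- cbind(match(pairs$a, nodes), match(pairs$b, nodes))
  d <- abs(a1 - a2)[idx]
  thr <- stats::quantile(d, t_edge, names = FALSE)
  keep <- which(d > thr)
  if (length(keep) == 0)
    stop2("no edge exceeds the ", t_edge, " quantile of |difference|; ",
          "lower the threshold (condition networks may be identical)")
  keep <- keep[order(-d[keep], pairs$a[keep], pairs$b[keep])]
  edge_set(pairs$a[keep], pairs$b[keep])
}

#' Tune node and edge selection by stratified cross-validation
#'
#' Every (n_nodes, t_edge) pair on the grid is scored by stratified k-fold
#' cross-validation inside the training set, running the fast Node Product
#' path per fold (node selection, condition networks, edge selection,
#' Node Product individual networks, edge-level PPN, precomputed-kernel
#' SVM) and averaging the held-out macro F1. The SVM cost is searched over
#' `c_grid` within the same folds. Ties go to the smaller n_nodes, then
#' the smaller t_edge.
#'
#' @param m Training feature matrix (one modality).
#' @param labels Named label vector.
#' @param n_nodes_grid,t_edge_grid Selection grids.
#' @param c_grid SVM cost grid.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param K,sigma Affinity parameters for the fold-level edge PPNs.
#' @param condition_method Passed to [condition_networks()].
#' @return List with `n_nodes`, `t_edge`, `score` (mean CV macro F1) and
#'   the full `grid` score table.
#' @export
tune_selection <- function(m, labels, n_nodes_grid = seq(100, 1400, 100),
                           t_edge_grid = c(0.25, 0.5, 0.75),
                           c_grid = 10^(1:5), folds = 5, seed = 1,
                           K = 20, sigma = 0.5,
                           condition_method = "pearson") {
  if (length(n_nodes_grid) == 0 || length(t_edge_grid) == 0)
    stop2("selection grids must be non-empty")
  labels <- labels[rownames(m)]
  if (any(table(labels) < folds))
    stop2("need at least ", folds, " samples per class for ", folds,
          "-fold tuning")
  n_nodes_grid <- sort(unique(pmin(n_nodes_grid, ncol(m))))
  fold_id <- stratified_folds(labels, folds, derive_seed(seed, "tune_cv"))
  grid <- expand.grid(n_nodes = n_nodes_grid, t_edge = t_edge_grid)
  grid$score <- NA_real_
  for (g in seq_len(nrow(grid))) {
    fold_scores <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m_tr <- m[tr, , drop = FALSE]
      m_te <- m[!tr, , drop = FALSE]
      f1 <- tryCatch({
        nodes <- select_top_nodes(m_tr, grid$n_nodes[g])
        cond <- condition_networks(m_tr, labels[tr], nodes,
                                   method = condition_method)
        edges <- select_edges(cond, grid$t_edge[g])
        sc <- min_max_scale_features(m_tr[, nodes, drop = FALSE])
        nets_tr <- node_product_networks(sc$values, edges)
        nets_te <- node_product_networks(
          apply_min_max(m_te, sc$ranges), edges)
        rng <- scale_edge_weights_global(nets_tr)
        nets_te <- scale_edge_weights_global(nets_te, range = rng$range)
        ppn <- normalize_ppn(edge_ppn(rng, nets_te,
                                      K = min(K, nrow(m_tr) - 1),
                                      sigma = sigma))
        best <- -Inf
        for (C in c_grid) {
          model <- svm_fit_kernel(ppn$train, labels[tr], C)
          pred <- predict_ppn(model, ppn$test)
          best <- max(best, macro_f1(labels[!tr], pred)$macro)
          if (best >= 1) break
        }
        best
      }, error = function(e) NA_real_)
      f1
    }, numeric(1))
    grid$score[g] <- mean(fold_scores, na.rm = TRUE)
  }
  if (all(is.na(grid$score))) stop2("all grid evaluations failed")
  ord <- order(-grid$score, grid$n_nodes, grid$t_edge)
  best <- grid[ord[1], ]
  list(n_nodes = best$n_nodes, t_edge = best$t_edge, score = best$score,
       grid = grid)
}
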