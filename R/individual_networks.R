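#' Construct a canonical edge set
#'
#' Unordered feature pairs stored with `a < b` lexicographically; self-pairs
#' and duplicates are rejected.
#'
#' @param a,b Character vectors of endpoint feature IDs.
#' @return A data.frame of class `"edge_set"` with columns `a`, `b`.
#' @export
edge_set <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop2("endpoint vectors differ in length")
  if (any(a == b)) stop2("self-pairs are not allowed in an edge set")
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "|")
  if (anyDuplicated(key))
    stop2("duplicate edges: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(data.frame(a = a, b = b, stringsAsFactors = FALSE),
            class = c("edge_set", "data.frame"))
}

#' All feature pairs of a node list
#' @param nodes Character vector of feature IDs.
#' @return An [edge_set()] with all `choose(p, 2)` pairs.
#' @export
all_edges <- function(nodes) {
  pr <- upper_pairs(nodes)
  edge_set(pr$a, pr$b)
}

edge_ids <- function(edges) paste(edges$a, edges$b, sep = "|")

check_edge_nodes <- function(edges, node_ids) {
  missing <- setdiff(unique(c(edges$a, edges$b)), node_ids)
  if (length(missing))
    stop2("edge endpoints absent from the matrix: ",
          paste(utils::head(missing, 5), collapse = ", "))
}

#' Min-max scale feature columns to [0, 1]
#'
#' Each feature column is mapped by `(x - min) / (max - min)` using its own
#' minimum and maximum. The per-feature ranges are returned so held-out
#' samples can be scaled with training statistics (see [apply_min_max()]).
#'
#' @param m Feature matrix (samples x features).
#' @return List with `values` (scaled matrix) and `ranges` (data.frame
#'   `feature`, `min`, `max`).
#' @export
min_max_scale_features <- function(m) {
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  const <- maxs <= mins
  if (any(const))
    stop2("constant feature(s) cannot be min-max scaled (remove during ",
          "node selection): ", paste(utils::head(colnames(m)[const], 5),
                                     collapse = ", "))
  values <- sweep(sweep(m, 2, mins, `-`), 2, maxs - mins, `/`)
  attr(values, "modality") <- attr(m, "modality")
  list(values = values,
       ranges = data.frame(feature = colnames(m), min = mins, max = maxs,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Scale new samples with stored (training) min-max ranges
#'
#' Values falling outside the training range scale outside [0, 1] and are
#' clipped back, so products of scaled values stay in [0, 1].
#'
#' @param m Feature matrix to scale.
#' @param ranges Ranges returned by [min_max_scale_features()].
#' @param clip Clip scaled values to [0, 1] (default `TRUE`).
#' @return Scaled matrix over the features listed in `ranges`.
#' @export
apply_min_max <- function(m, ranges, clip = TRUE) {
  missing <- setdiff(ranges$feature, colnames(m))
  if (length(missing))
    stop2("matrix lacks feature(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  m <- m[, ranges$feature, drop = FALSE]
  values <- sweep(sweep(m, 2, ranges$min, `-`), 2,
                  ranges$max - ranges$min, `/`)
  if (clip) values <- pmin(pmax(values, 0), 1)
  values
}

new_individual_nets <- function(edges, weights, method, scaled = FALSE,
                                range = NULL) {
  stopifnot(nrow(weights) == nrow(edges))
  rownames(weights) <- edge_ids(edges)
  structure(list(edges = edges, weights = weights, method = method,
                 scaled = scaled, range = range),
            class = "individual_nets")
}

#' @export
print.individual_nets <- function(x, ...) {
  cat("Individual networks (", x$method, "): ", ncol(x$weights),
      " samples, ", nrow(x$edges), " edges, ",
      if (x$scaled) "scaled to [0,1]" else "unscaled", "\n", sep = "")
  invisible(x)
}

#' Node Product individual networks
#'
#' For each sample, the weight of edge (i, j) is the product of the
#' sample's min-max-scaled values of features i and j, so weights lie in
#' [0, 1].
#'
#' @param m_scaled Feature matrix already scaled to [0, 1] (see
#'   [min_max_scale_features()] / [apply_min_max()]).
#' @param edges An [edge_set()] over the matrix's features.
#' @return An `individual_nets` collection (edges x samples weight matrix).
#' @export
node_product_networks <- function(m_scaled, edges) {
  check_edge_nodes(edges, colnames(m_scaled))
  if (any(m_scaled < -1e-9) || any(m_scaled > 1 + 1e-9))
    stop2("node_product_networks expects values scaled to [0, 1]")
  w <- t(m_scaled[, edges$a, drop = FALSE] * m_scaled[, edges$b, drop = FALSE])
  colnames(w) <- rownames(m_scaled)
  new_individual_nets(edges, w, "node_product", scaled = TRUE)
}

#' Pearson co-expression adjacency over a node set
#'
#' The aggregate model used by LIONESS and by condition-specific networks:
#' feature-by-feature Pearson correlation with a zero diagonal.
#'
#' @param m Feature matrix (samples x features).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pearson_adjacency <- function(m) {
  if (nrow(m) < 3) stop2("need at least 3 samples for a correlation network")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop2("zero-variance feature(s): ",
          paste(utils::head(colnames(m)[sds == 0], 5), collapse = ", "))
  a <- stats::cor(m)
  diag(a) <- 0
  a
}

#' Aggregate network restricted to an edge set
#'
#' @param m Feature matrix.
#' @param edges An [edge_set()].
#' @param agg_fun Function mapping a feature matrix to a symmetric
#'   adjacency over its columns; defaults to [pearson_adjacency()].
#' @return Named numeric vector of edge weights in edge-set order.
#' @export
aggregate_network <- function(m, edges, agg_fun = pearson_adjacency) {
  check_edge_nodes(edges, colnames(m))
  adj <- agg_fun(m)
  idx <- cbind(match(edges$a, colnames(m)), match(edges$b, colnames(m)))
  stats::setNames(adj[idx], edge_ids(edges))
}

#' LIONESS individual networks for a training panel
#'
#' Linear interpolation to obtain network estimates for single samples:
#' with `e_all` the aggregate network on all N samples and `e_wo` the
#' aggregate on all samples but x, sample x's edge weight is
#' `N * (e_all - e_wo) + e_wo`. When the aggregate is a per-sample mean of
#' any edge statistic, this reconstructs each sample's own statistic
#' exactly.
#'
#' @param m Feature matrix (training panel, N >= 4).
#' @param edges An [edge_set()].
#' @param agg_fun Aggregate model, as in [aggregate_network()].
#' @return An unscaled `individual_nets` collection.
#' @export
lioness_networks <- function(m, edges, agg_fun = pearson_adjacency) {
  n <- nrow(m)
  if (n < 4) stop2("LIONESS needs at least 4 samples ",
                   "(leave-one-out aggregate needs >= 3)")
  if (identical(agg_fun, pearson_adjacency))
    return(lioness_pearson_fast(m, edges))
  e_all <- aggregate_network(m, edges, agg_fun)
  w <- vapply(seq_len(n), function(x) {
    e_wo <- tryCatch(
      aggregate_network(m[-x, , drop = FALSE], edges, agg_fun),
      error = function(e) stop2("aggregate failed when leaving out sample '",
                                rownames(m)[x], "': ", conditionMessage(e)))
    n * (e_all - e_wo) + e_wo
  }, numeric(nrow(edges)))
  colnames(w) <- rownames(m)
  new_individual_nets(edges, w, "lioness")
}

# Exact leave-one-out Pearson LIONESS from running sums: for each edge the
# full-panel and leave-one-out correlations come from the raw moments
# (sum x, sum x^2, sum xy), so the whole panel costs O(N * |edges|) instead
# of N correlation matrices.
lioness_pearson_fast <- function(m, edges) {
  n <- nrow(m)
  check_edge_nodes(edges, colnames(m))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop2("zero-variance feature(s): ",
          paste(utils::head(colnames(m)[sds == 0], 5), collapse = ", "))
  ma <- m[, edges$a, drop = FALSE]
  mb <- m[, edges$b, drop = FALSE]
  s1a <- colSums(ma); s1b <- colSums(mb)
  s2a <- colSums(ma^2); s2b <- colSums(mb^2)
  sab <- colSums(ma * mb)
  r_from_moments <- function(n, s1a, s1b, s2a, s2b, sab) {
    num <- n * sab - s1a * s1b
    den <- sqrt(pmax(n * s2a - s1a^2, 0) * pmax(n * s2b - s1b^2, 0))
    if (any(den == 0)) stop2("zero variance in a leave-one-out panel")
    num / den
  }
  e_all <- r_from_moments(n, s1a, s1b, s2a, s2b, sab)
  w <- vapply(seq_len(n), function(x) {
    xa <- ma[x, ]; xb <- mb[x, ]
    e_wo <- r_from_moments(n - 1, s1a - xa, s1b - xb,
                           s2a - xa^2, s2b - xb^2, sab - xa * xb)
    n * (e_all - e_wo) + e_wo
  }, numeric(nrow(edges)))
  colnames(w) <- rownames(m)
  new_individual_nets(edges, w, "lioness")
}

#' LIONESS networks for held-out samples via one-at-a-time panels
#'
#' Each test sample is appended alone to the training panel; LIONESS is
#' recomputed on that temporary (N+1)-sample panel. Both the test sample's
#' network and the panel's refreshed training networks are returned, since
#' test-to-train graph distances are taken within the temporary panel.
#'
#' @param m_train Training feature matrix.
#' @param m_test Held-out feature matrix (same features).
#' @param edges An [edge_set()].
#' @param agg_fun Aggregate model.
#' @return Named list, one element per test sample, each with `test`
#'   (single-column `individual_nets`) and `train` (refreshed training
#'   networks from the same panel).
#' @export
lioness_test_networks <- function(m_train, m_test, edges,
                                  agg_fun = pearson_adjacency) {
  missing <- setdiff(colnames(m_train), colnames(m_test))
  if (length(missing))
    stop2("test matrix lacks feature(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  m_test <- m_test[, colnames(m_train), drop = FALSE]
  out <- lapply(seq_len(nrow(m_test)), function(t_i) {
    panel <- rbind(m_train, m_test[t_i, , drop = FALSE])
    nets <- lioness_networks(panel, edges, agg_fun)
    n_tr <- nrow(m_train)
    list(test = new_individual_nets(
           edges, nets$weights[, n_tr + 1L, drop = FALSE], "lioness"),
         train = new_individual_nets(
           edges, nets$weights[, seq_len(n_tr), drop = FALSE], "lioness"))
  })
  names(out) <- rownames(m_test)
  out
}

#' Globally min-max scale individual-network edge weights
#'
#' A single affine map, built from the minimum and maximum weight across
#' all networks, sends every weight into [0, 1]; the shared map preserves
#' the ordering of weights between individuals. When a stored `range` is
#' supplied (scaling held-out networks with training statistics), out-of-
#' range values are clipped to [0, 1].
#'
#' @param nets An `individual_nets` collection.
#' @param range Optional `c(min, max)` from a previous call.
#' @return The collection with scaled weights and the `range` recorded.
#' @export
scale_edge_weights_global <- function(nets, range = NULL) {
  stopifnot(inherits(nets, "individual_nets"))
  clip <- !is.null(range)
  if (is.null(range)) {
    range <- c(min(nets$weights), max(nets$weights))
    if (range[2] <= range[1])
      stop2("all edge weights are equal; global scaling is undefined")
  }
  w <- (nets$weights - range[1]) / (range[2] - range[1])
  if (clip) w <- pmin(pmax(w, 0), 1)
  new_individual_nets(nets$edges, w, nets$method, scaled = TRUE,
                      range = range)
}
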