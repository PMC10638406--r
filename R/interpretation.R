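#' Edge-weight matrix (edges x samples) from individual networks
#'
#' @param nets An `individual_nets` collection.
#' @return Numeric matrix; rows are `a|b` edge IDs, columns are sample IDs
#'   in sorted order.
#' @export
edge_matrix <- function(nets) {
  stopifnot(inherits(nets, "individual_nets"))
  m <- nets$weights[, order(colnames(nets$weights)), drop = FALSE]
  check_finite(m, "edge matrix")
  m
}

#' Per-edge differential co-expression with moderated t-statistics
#'
#' Fits, for every row (edge or gene), the two-group linear model of
#' weight on class and shrinks the residual variances towards a common
#' prior by empirical Bayes before forming t-statistics: the posterior
#' variance is `(d0 * s0^2 + d * s^2) / (d0 + d)` with the prior
#' `(d0, s0^2)` estimated across rows by moment matching on the log
#' residual variances. The coefficient is `mean(group1) - mean(group2)`
#' with groups in sorted label order. P-values are two-sided from the t
#' distribution on `d + d0` degrees of freedom, adjusted by
#' Benjamini-Hochberg.
#'
#' @param m1 Numeric matrix, rows = edges (or genes), columns = samples.
#' @param groups Named label vector with exactly two classes covering the
#'   columns of `m1`.
#' @param prior_df Optional override of the prior degrees of freedom; `0`
#'   disables moderation (ordinary t-statistics).
#' @return data.frame sorted by decreasing `|t|` with columns `id`,
#'   `coef`, `ave`, `t`, `p_value`, `adj_p`, `df_total`; the estimated
#'   prior is attached as attributes `df_prior` and `s2_prior`.
#' @export
moderated_t_stats <- function(m1, groups, prior_df = NULL) {
  groups <- groups[colnames(m1)]
  if (any(is.na(groups))) stop2("groups missing for some samples")
  classes <- sort(unique(as.character(groups)))
  if (length(classes) != 2)
    stop2("moderated t-statistics are defined for exactly two groups")
  n1 <- sum(groups == classes[1]); n2 <- sum(groups == classes[2])
  if (min(n1, n2) < 2)
    stop2("each group needs at least 2 samples")
  i1 <- groups == classes[1]; i2 <- groups == classes[2]
  mu1 <- rowMeans(m1[, i1, drop = FALSE])
  mu2 <- rowMeans(m1[, i2, drop = FALSE])
  ss <- rowSums((m1[, i1, drop = FALSE] - mu1)^2) +
    rowSums((m1[, i2, drop = FALSE] - mu2)^2)
  d <- n1 + n2 - 2
  s2 <- ss / d
  coef <- mu1 - mu2
  se_unit <- sqrt(1 / n1 + 1 / n2)
  if (is.null(prior_df)) {
    sq <- limma::squeezeVar(s2, df = d)
    d0 <- sq$df.prior
    s02 <- sq$var.prior
    s2_post <- sq$var.post
  } else {
    d0 <- prior_df
    if (d0 == 0) {
      s02 <- NA_real_
      s2_post <- s2
    } else {
      s02 <- limma::squeezeVar(s2, df = d)$var.prior
      s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
                 else (d0 * s02 + d * s2) / (d0 + d)
    }
  }
  df_total <- d + d0
  tt <- coef / (sqrt(s2_post) * se_unit)
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  out <- data.frame(id = rownames(m1), coef = coef, ave = rowMeans(m1),
                    t = tt, p_value = p,
                    adj_p = stats::p.adjust(p, "BH"),
                    df_total = df_total, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$t), out$id), ]
  rownames(out) <- NULL
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s02
  attr(out, "s2") <- s2
  attr(out, "df_residual") <- d
  attr(out, "classes") <- classes
  out
}

#' Network of the most differentially co-expressed edges
#'
#' Builds a graph over the genes touched by the top `n` edges of an edge
#' statistics table. Edge attributes carry the sign of the group
#' difference (`direction`, a color key) and `|coef|` (width); node
#' attributes carry gene-level t-statistics from a parallel expression
#' analysis, masked to neutral (`"white"`) when `|t|` falls below
#' `node_t_threshold`.
#'
#' @param stats Edge table from [moderated_t_stats()] with `a|b` edge IDs.
#' @param n Number of top edges (default 50).
#' @param gene_stats Optional named vector of gene-level t-statistics.
#' @param node_t_threshold Mask threshold for node t-statistics.
#' @return List with `graph` (igraph), `edges` and `nodes` data.frames.
#' @export
top_edges_network <- function(stats, n = 50, gene_stats = NULL,
                              node_t_threshold = 1.5) {
  if (nrow(stats) < n)
    stop2("table has ", nrow(stats), " edges; cannot take top ", n)
  top <- stats[seq_len(n), ]
  ends <- strsplit(top$id, "|", fixed = TRUE)
  edges_df <- data.frame(
    node_a = vapply(ends, `[`, "", 1), node_b = vapply(ends, `[`, "", 2),
    coef = top$coef, t = top$t, adj_p = top$adj_p,
    direction = ifelse(top$coef >= 0, "group1_higher", "group2_higher"),
    width = abs(top$coef), stringsAsFactors = FALSE)
  genes <- sort(unique(c(edges_df$node_a, edges_df$node_b)))
  node_t <- if (is.null(gene_stats)) rep(NA_real_, length(genes))
            else unname(gene_stats[genes])
  nodes_df <- data.frame(
    gene = genes, t = node_t,
    color = ifelse(is.na(node_t) | abs(node_t) < node_t_threshold, "white",
                   ifelse(node_t >= 0, "group1_higher", "group2_higher")),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges_df, directed = FALSE,
                                     vertices = nodes_df)
  list(graph = g, edges = edges_df, nodes = nodes_df)
}

#' Write an annotated network as TSV edge list, node table and GraphML
#' @param net Result of [top_edges_network()].
#' @param basename Output path prefix; writes `<basename>_edges.tsv`,
#'   `<basename>_nodes.tsv`, `<basename>.graphml`.
#' @export
write_network <- function(net, basename) {
  utils::write.table(net$edges, paste0(basename, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, paste0(basename, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(net$graph, paste0(basename, ".graphml"),
                      format = "graphml")
  invisible(basename)
}

#' Genes of the largest connected component
#'
#' @param net An igraph object or the list from [top_edges_network()].
#' @return Sorted character vector of gene IDs in the largest component;
#'   size ties are broken towards the component containing the
#'   lexicographically smallest gene.
#' @export
largest_component <- function(net) {
  g <- if (inherits(net, "igraph")) net else net$graph
  if (igraph::vcount(g) == 0) stop2("empty network")
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  members <- lapply(cand, function(k)
    sort(names(comp$membership)[comp$membership == k]))
  members[[order(vapply(members, `[`, "", 1))[1]]]
}

#' Preranked gene-set enrichment analysis
#'
#' Classical weighted Kolmogorov-Smirnov running-sum enrichment (weight =
#' ranking statistic, exponent 1) with a gene-label permutation null, as
#' implemented by the fgsea permutation routine. Sets smaller than
#' `min_size` after intersection with the ranking are dropped; q-values
#' are Benjamini-Hochberg over the tested sets.
#'
#' @param ranked Named numeric vector (gene -> signed statistic, e.g.
#'   moderated t); no duplicate names.
#' @param sets Gene-set collection from [read_gmt()] (named list).
#' @param min_size Minimum post-intersection set size (default 10).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return data.frame with `pathway`, `size`, `es`, `nes`, `p_value`,
#'   `q_value`, `leading_edge`.
#' @export
gsea_preranked <- function(ranked, sets, min_size = 10, n_perm = 5000,
                           seed = 1) {
  if (length(ranked) == 0) stop2("empty ranking")
  if (anyDuplicated(names(ranked)))
    stop2("duplicate genes in the ranking")
  if (n_perm < 100) stop2("use at least 100 permutations")
  res <- with_seed(derive_seed(seed, "gsea"), suppressWarnings(
    fgsea::fgseaSimple(pathways = sets, stats = ranked,
                       minSize = min_size, maxSize = length(ranked),
                       nperm = n_perm, gseaParam = 1, nproc = 0)))
  out <- data.frame(pathway = res$pathway, size = res$size, es = res$ES,
                    nes = res$NES, p_value = res$pval, q_value = res$padj,
                    leading_edge = vapply(res$leadingEdge, paste,
                                          character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$pathway), ]
}
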