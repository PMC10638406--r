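#' Bundle train/test matrices and labels for the pipeline
#'
#' @param train Named list of training feature matrices (one per modality).
#' @param test Named list of test feature matrices (same names), or NULL.
#' @param labels_train Named label vector covering the training samples.
#' @param labels_test Optional named label vector for scoring.
#' @return A `"ppn_dataset"` list.
#' @export
ppn_dataset <- function(train, test = NULL, labels_train,
                        labels_test = NULL) {
  if (is.null(names(train))) names(train) <- paste0("mod", seq_along(train))
  labels_train <- label_vector(labels_train)
  for (m in train)
    if (!all(rownames(m) %in% names(labels_train)))
      stop2("labels missing for some training samples")
  if (!is.null(test) && !setequal(names(test), names(train)))
    stop2("train and test modalities differ")
  structure(list(train = train, test = test, labels_train = labels_train,
                 labels_test = labels_test), class = "ppn_dataset")
}

as_ppn_dataset <- function(x) {
  if (inherits(x, "ppn_dataset")) return(x)
  if (is.list(x) && !is.null(x$train) && !is.null(x$labels_train))
    return(ppn_dataset(x$train, x$test, x$labels_train, x$labels_test))
  stop2("cannot interpret data as a ppn_dataset")
}

node_level_ppn <- function(m_tr, m_te, node_sim, K = 20, sigma_affinity = 0.05,
                           sigma_gaussian = 1000) {
  switch(node_sim,
    affinity = affinity_ppn(m_tr, m_te, K = min(K, nrow(m_tr) - 1),
                            sigma = sigma_affinity),
    gaussian = gaussian_ppn(m_tr, m_te, sigma = sigma_gaussian),
    spearman = spearman_ppn(m_tr, m_te),
    stop2("unknown node similarity: ", node_sim))
}

# Node selection + condition networks + edge selection + individual
# networks + edge PPN for one (possibly concatenated) matrix.
edge_level_ppn <- function(m_tr, m_te, labels_tr, n_nodes, t_edge,
                           edge_method, K = 20, sigma = 0.5,
                           condition_method = "pearson",
                           return_artifacts = FALSE) {
  nodes <- if (is.null(n_nodes) || n_nodes >= ncol(m_tr)) colnames(m_tr)
           else select_top_nodes(m_tr, n_nodes)
  cond <- condition_networks(m_tr, labels_tr, nodes,
                             method = condition_method)
  edges <- select_edges(cond, t_edge)
  m_tr_sel <- m_tr[, nodes, drop = FALSE]
  if (edge_method == "node_product") {
    sc <- min_max_scale_features(m_tr_sel)
    nets_tr <- node_product_networks(sc$values, edges)
    nets_tr <- scale_edge_weights_global(nets_tr)
    nets_te <- NULL
    if (!is.null(m_te)) {
      nets_te <- node_product_networks(apply_min_max(m_te, sc$ranges), edges)
      nets_te <- scale_edge_weights_global(nets_te, range = nets_tr$range)
    }
  } else if (edge_method == "lioness") {
    nets_tr <- lioness_networks(m_tr_sel, edges)
    rng <- scale_edge_weights_global(nets_tr)
    nets_te <- NULL
    if (!is.null(m_te)) {
      panels <- lioness_test_networks(m_tr_sel,
                                      m_te[, nodes, drop = FALSE], edges)
      nets_te <- lapply(panels, function(p) list(
        test = scale_edge_weights_global(p$test, range = rng$range),
        train = scale_edge_weights_global(p$train, range = rng$range)))
    }
    nets_tr <- rng
  } else stop2("unknown edge method: ", edge_method)
  ppn <- edge_ppn(nets_tr, nets_te, K = min(K, ncol(nets_tr$weights) - 1),
                  sigma = sigma)
  if (return_artifacts)
    list(ppn = ppn, nodes = nodes, edges = edges, nets_train = nets_tr,
         nets_test = nets_te)
  else list(ppn = ppn, nodes = nodes, edges = edges)
}

# Normalized PPN for one modality at the requested level.
modality_ppn <- function(m_tr, m_te, labels_tr, level, node_sim, edge_method,
                         sel, K = 20, sigma = 0.5,
                         condition_method = "pearson") {
  if (level == "nodes")
    return(normalize_ppn(node_level_ppn(m_tr, m_te, node_sim, K = K)))
  ep <- edge_level_ppn(m_tr, m_te, labels_tr, sel$n_nodes, sel$t_edge,
                       edge_method, K = K, sigma = sigma,
                       condition_method = condition_method)
  if (level == "edges") return(normalize_ppn(ep$ppn))
  combine_node_edge(normalize_ppn(node_level_ppn(m_tr, m_te, node_sim,
                                                 K = K)),
                    normalize_ppn(ep$ppn))
}

# Square PPN over train+test samples (used by SNF, which diffuses a full
# sample-by-sample graph; labels play no part).
modality_ppn_square <- function(m_tr, m_te, labels_tr, level, node_sim,
                                edge_method, sel, K = 20, sigma = 0.5,
                                condition_method = "pearson") {
  n_all <- nrow(m_tr) + if (is.null(m_te)) 0 else nrow(m_te)
  node_square <- function() {
    m_all <- rbind(m_tr, m_te)
    node_level_ppn(m_all, NULL, node_sim, K = min(K, n_all - 1))$train
  }
  edge_square <- function() {
    ep <- edge_level_ppn(m_tr, m_te, labels_tr, sel$n_nodes, sel$t_edge,
                         edge_method, K = K, sigma = sigma,
                         condition_method = condition_method,
                         return_artifacts = TRUE)
    w_te <- if (is.null(ep$nets_test)) NULL
            else if (inherits(ep$nets_test, "individual_nets"))
              ep$nets_test$weights
            else do.call(cbind, lapply(ep$nets_test,
                                       function(p) p$test$weights))
    w_all <- cbind(ep$nets_train$weights, w_te)
    d <- edge_distance_matrix(w_all)
    affinity_from_dist(d, K = min(K, n_all - 1), sigma = sigma)$train
  }
  if (level == "nodes") return(node_square())
  if (level == "edges") return(edge_square())
  ns <- normalize_ppn(node_square())
  es <- normalize_ppn(edge_square())
  (ns + es) / 2
}

resolve_selection <- function(data, config, modality) {
  sel <- config$selection[[modality]]
  if (!is.null(sel)) return(sel)
  tuned <- tune_selection(
    data$train[[modality]], data$labels_train,
    n_nodes_grid = config$n_nodes_grid, t_edge_grid = config$t_edge_grid,
    c_grid = config$c_grid, folds = config$folds,
    seed = derive_seed(config$seed, paste0("tune_", modality)))
  list(n_nodes = tuned$n_nodes, t_edge = tuned$t_edge)
}

#' Run the full classification workflow for one configured variation
#'
#' Executes selection, individual-network construction, PPN construction,
#' fusion, SVM training, prediction and macro-F1 scoring for the variation
#' described by `config` (level of information, node similarity, edge
#' method and fusion mode). Combinations the workflow does not define
#' (e.g. modality fusion with a single modality, or late fusion outside
#' the nodes-and-edges level) raise an error before any work is done.
#'
#' @param data A [ppn_dataset()] (or the list returned by
#'   [simulate_dataset()]). Ignored when `config` carries file paths.
#' @param config A [run_config()]-style list. Recognized extras:
#'   `modality` (which modality to use when `fusion = "none"`),
#'   `selection` (named per-modality list of `n_nodes`/`t_edge`; tuned by
#'   cross-validation when absent and the level uses edges),
#'   `c_select` (`"cv"` or `"train"`), `condition_method`.
#' @return A `"ppn_result"` list: `metrics`, `predictions`, `model`,
#'   `ppn`, `selection`, `contribution` (late fusion only), `config`.
#' @export
run_pipeline <- function(data = NULL, config) {
  if (is.null(data)) {
    if (is.null(config$modalities)) stop2("no data and no configured paths")
    train <- lapply(names(config$modalities), function(nm)
      read_feature_matrix(config$modalities[[nm]], nm))
    names(train) <- names(config$modalities)
    test <- NULL
    if (!is.null(config$modalities_test)) {
      test <- lapply(names(config$modalities_test), function(nm)
        read_feature_matrix(config$modalities_test[[nm]], nm))
      names(test) <- names(config$modalities_test)
    }
    labels <- read_labels(config$labels)
    data <- ppn_dataset(train, test, labels[rownames(train[[1]])],
                        if (!is.null(test))
                          labels[intersect(names(labels),
                                           rownames(test[[1]]))])
  }
  data <- as_ppn_dataset(data)
  level <- config$level %||% "nodes"
  fusion <- config$fusion %||% "none"
  node_sim <- config$node_similarity %||% "spearman"
  edge_method <- config$edge_method %||% "node_product"
  c_select <- config$c_select %||% "cv"
  cond_method <- config$condition_method %||% "pearson"
  c_grid <- config$c_grid %||% 10^(1:5)
  folds <- config$folds %||% 5
  seed <- config$seed %||% 1
  sigma_edge <- config$sigma_edge %||% 0.5
  mods <- names(data$train)
  needs_edges <- level %in% c("edges", "nodes_and_edges")

  if (fusion == "none" && length(mods) > 1 && is.null(config$modality))
    stop2("fusion = 'none' with several modalities: set config$modality")
  if (fusion != "none" && length(mods) < 2)
    stop2("combination not defined: modality fusion requires >= 2 modalities")
  if (fusion == "late" && level != "nodes_and_edges")
    stop2("combination not defined: late fusion applies to the ",
          "nodes-and-edges level (a majority vote over a single level ",
          "and modality adds no information)")

  selection <- list()
  if (needs_edges) {
    use_mods <- if (fusion == "none") (config$modality %||% mods[1]) else mods
    for (nm in use_mods) selection[[nm]] <- resolve_selection(data, config, nm)
  }
  labels_tr <- data$labels_train
  truth <- data$labels_test
  contribution <- NULL
  model <- NULL

  fit_and_predict <- function(ppn) {
    ppn_fit <- if (ppn$normalized) ppn else normalize_ppn(ppn)
    model <<- train_svm(ppn_fit$train, labels_tr, c_grid = c_grid,
                        folds = folds, seed = derive_seed(seed, "svm"),
                        c_select = c_select)
    pred <- if (!is.null(ppn_fit$test)) predict_ppn(model, ppn_fit$test)
    list(ppn = ppn_fit, pred = pred)
  }

  if (fusion == "none") {
    nm <- config$modality %||% mods[1]
    ppn <- modality_ppn(data$train[[nm]], data$test[[nm]], labels_tr, level,
                        node_sim, edge_method, selection[[nm]],
                        sigma = sigma_edge, condition_method = cond_method)
    out <- fit_and_predict(ppn)
  } else if (fusion == "early") {
    n_nodes <- if (needs_edges) lapply(selection, `[[`, "n_nodes")
    m_tr <- early_fusion(data$train, n_nodes)
    m_te <- if (!is.null(data$test)) {
      te <- early_fusion(data$test, NULL)
      te[, intersect(colnames(m_tr), colnames(te)), drop = FALSE]
    }
    t_edge <- if (needs_edges)
      config$t_edge_early %||% selection[[1]]$t_edge
    sel <- list(n_nodes = NULL, t_edge = t_edge)
    ppn <- modality_ppn(m_tr, m_te, labels_tr, level, node_sim, edge_method,
                        sel, sigma = sigma_edge,
                        condition_method = cond_method)
    out <- fit_and_predict(ppn)
  } else if (fusion == "intermediate_average") {
    ppns <- lapply(mods, function(nm)
      modality_ppn(data$train[[nm]], data$test[[nm]], labels_tr, level,
                   node_sim, edge_method, selection[[nm]],
                   sigma = sigma_edge, condition_method = cond_method))
    out <- fit_and_predict(intermediate_average(ppns))
  } else if (fusion == "intermediate_snf") {
    squares <- lapply(mods, function(nm)
      modality_ppn_square(data$train[[nm]], data$test[[nm]], labels_tr,
                          level, node_sim, edge_method, selection[[nm]],
                          sigma = sigma_edge,
                          condition_method = cond_method))
    n_all <- nrow(squares[[1]])
    fused <- snf_fuse(squares, K = min(20, n_all - 1))
    tr_ids <- rownames(data$train[[1]])
    te_ids <- setdiff(rownames(fused), tr_ids)
    fused_n <- normalize_ppn(fused)
    ppn <- new_ppn(fused_n[tr_ids, tr_ids],
                   if (length(te_ids)) fused_n[te_ids, tr_ids, drop = FALSE],
                   if (length(te_ids))
                     stats::setNames(rep(1, length(te_ids)), te_ids),
                   kind = "fused", normalized = TRUE)
    out <- fit_and_predict(ppn)
  } else if (fusion == "late") {
    if (is.null(data$test))
      stop2("late fusion needs test samples to vote on")
    preds <- list()
    for (nm in mods) {
      ppn_n <- normalize_ppn(node_level_ppn(data$train[[nm]],
                                            data$test[[nm]], node_sim))
      ppn_e <- normalize_ppn(edge_level_ppn(
        data$train[[nm]], data$test[[nm]], labels_tr,
        selection[[nm]]$n_nodes, selection[[nm]]$t_edge, edge_method,
        sigma = sigma_edge, condition_method = cond_method)$ppn)
      for (part in c("node", "edge")) {
        ppn_part <- if (part == "node") ppn_n else ppn_e
        m <- train_svm(ppn_part$train, labels_tr, c_grid = c_grid,
                       folds = folds,
                       seed = derive_seed(seed, paste0("svm_", nm, part)),
                       c_select = c_select)
        preds[[paste(nm, part, sep = "_")]] <- predict_ppn(m, ppn_part$test)
      }
    }
    vote <- late_fusion_majority(preds, seed = derive_seed(seed, "late"))
    contribution <- vote$contribution
    out <- list(ppn = NULL, pred = vote$labels)
  } else stop2("unknown fusion mode: ", fusion)

  metrics <- if (!is.null(out$pred) && !is.null(truth))
    macro_f1(truth, out$pred)
  result <- structure(
    list(metrics = metrics, predictions = out$pred, truth = truth,
         model = model, ppn = out$ppn, selection = selection,
         contribution = contribution, config = config),
    class = "ppn_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.ppn_result <- function(x, ...) {
  cat("Pipeline result (level=", x$config$level %||% "nodes",
      ", fusion=", x$config$fusion %||% "none", ")\n", sep = "")
  if (!is.null(x$metrics)) {
    cat("  macro F1:", round(x$metrics$macro, 4), "\n")
    cat("  per-class F1:",
        paste(names(x$metrics$per_class),
              round(x$metrics$per_class, 4), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Predictions, per-class and macro F1, the training PPN, the late-fusion
#' contribution table when present, and a JSON run log.
#'
#' @param result A `"ppn_result"`.
#' @param out_dir Output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$predictions)) {
    df <- data.frame(sample_id = names(result$predictions),
                     predicted = unname(result$predictions))
    if (!is.null(result$truth))
      df$true <- unname(result$truth[df$sample_id])
    utils::write.table(df[order(df$sample_id), ],
                       file.path(out_dir, "predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$metrics)) {
    mf <- data.frame(class = c(names(result$metrics$per_class), "macro"),
                     f1 = c(unname(result$metrics$per_class),
                            result$metrics$macro))
    utils::write.table(mf, file.path(out_dir, "metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$ppn))
    write_ppn(result$ppn$train, file.path(out_dir, "train_ppn.tsv"))
  if (!is.null(result$contribution))
    utils::write.table(
      data.frame(set = names(result$contribution),
                 contribution_pct = unname(result$contribution)),
      file.path(out_dir, "contribution.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  log <- list(level = result$config$level, fusion = result$config$fusion,
              node_similarity = result$config$node_similarity,
              edge_method = result$config$edge_method,
              seed = result$config$seed,
              chosen_C = if (!is.null(result$model)) result$model$C,
              selection = result$selection,
              macro_f1 = if (!is.null(result$metrics)) result$metrics$macro)
  write_run_log(log, file.path(out_dir, "run_log.json"))
  invisible(out_dir)
}

#' Sweep workflow variations on one dataset
#'
#' Runs [run_pipeline()] over a grid of variations and collects macro F1
#' per combination, mirroring the heatmap layout of the workflow's
#' variation study. Undefined combinations are skipped.
#'
#' @param data A [ppn_dataset()].
#' @param config Base configuration (selection, grids, seed).
#' @param levels,node_sims,edge_methods,fusions Vectors of variations.
#' @return data.frame with one row per attempted variation.
#' @export
sweep_variations <- function(data, config,
                             levels = c("nodes", "edges", "nodes_and_edges"),
                             node_sims = "spearman",
                             edge_methods = "node_product",
                             fusions = c("none", "intermediate_average")) {
  grid <- expand.grid(level = levels, node_sim = node_sims,
                      edge_method = edge_methods, fusion = fusions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$level <- grid$level[i]
    cfg$node_similarity <- grid$node_sim[i]
    cfg$edge_method <- grid$edge_method[i]
    cfg$fusion <- grid$fusion[i]
    res <- tryCatch(run_pipeline(data, cfg), error = function(e) e)
    data.frame(grid[i, , drop = FALSE],
               macro_f1 = if (inherits(res, "error")) NA_real_
                          else res$metrics$macro,
               note = if (inherits(res, "error")) conditionMessage(res)
                      else "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
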