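#' Read a feature matrix (samples x features)
#'
#' Reads a delimited text file whose header row holds feature identifiers and
#' whose first column holds sample identifiers. The delimiter (tab or comma)
#' is auto-detected from the header line.
#'
#' @param path Path to a TSV/CSV file.
#' @param modality Short tag naming the data source (e.g. `"rna"`,
#'   `"histo"`); stored as an attribute and used to prefix feature IDs on
#'   early fusion.
#' @return A numeric matrix with sample IDs as rownames, feature IDs as
#'   colnames and a `"modality"` attribute.
#' @export
read_feature_matrix <- function(path, modality = "data") {
  if (!file.exists(path)) stop2("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop2("feature matrix needs >= 1 feature column: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop2("non-numeric values in feature column(s): ",
          paste(colnames(df)[-1][bad], collapse = ", "))
  }
  rownames(m) <- ids
  feature_matrix(m, modality = modality)
}

#' Validate and tag a feature matrix
#'
#' @param m Numeric matrix, samples in rows (rownames = sample IDs) and
#'   features in columns (colnames = feature IDs).
#' @param modality Modality tag.
#' @return The validated matrix with a `"modality"` attribute.
#' @export
feature_matrix <- function(m, modality = "data") {
  if (!is.matrix(m) || !is.numeric(m)) stop2("values must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop2("feature matrix needs sample rownames and feature colnames")
  if (anyDuplicated(rownames(m)))
    stop2("duplicate sample IDs: ",
          paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop2("duplicate feature IDs: ",
          paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!all(is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop2("missing/non-finite value at sample '", rownames(m)[idx[1]],
          "', feature '", colnames(m)[idx[2]], "'")
  }
  attr(m, "modality") <- modality
  m
}

#' Write a feature matrix to TSV
#' @param m Feature matrix (samples x features).
#' @param path Output path.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample label table
#'
#' Two-column delimited text: sample ID, class label. A header row is
#' detected and skipped when its second field is not repeated as a label.
#'
#' @param path Path to TSV/CSV.
#' @return Named character vector of labels (names = sample IDs).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop2("label table needs two columns (sample_id, label)")
  label_vector(stats::setNames(as.character(df[[2]]), as.character(df[[1]])))
}

#' Validate a label vector
#' @param labels Named character vector (names = sample IDs).
#' @return The validated vector.
#' @export
label_vector <- function(labels) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop2("labels must be named by sample ID")
  if (anyDuplicated(names(labels))) stop2("duplicate sample IDs in labels")
  labels <- stats::setNames(as.character(labels), names(labels))
  if (length(unique(labels)) < 2)
    stop2("need at least 2 distinct class labels")
  labels
}

#' Write labels to TSV
#' @param labels Named character vector.
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene IDs, all
#' tab-separated. Duplicate genes within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; each element carries a
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop2("GMT line ", k, " has fewer than 3 fields")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop2("GMT line ", k, ": empty gene set")
    attr(genes, "description") <- fields[2]
    sets[[fields[1]]] <- genes
  }
  sets
}

#' Write a Person-to-Person similarity matrix to TSV
#'
#' Rows and columns are labelled with sample IDs; rectangular test-by-train
#' matrices are written as-is.
#'
#' @param ppn Numeric matrix with sample-ID dimnames.
#' @param path Output path.
#' @export
write_ppn <- function(ppn, path) {
  if (is.null(rownames(ppn)) || is.null(colnames(ppn)))
    stop2("PPN must carry sample-ID dimnames")
  df <- data.frame(sample_id = rownames(ppn), ppn, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Person-to-Person similarity matrix written by [write_ppn()]
#' @param path Path to TSV.
#' @return Numeric matrix with sample-ID dimnames.
#' @export
read_ppn <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  check_finite(m, "PPN")
  m
}

#' Write an edge-weight table (edges x samples)
#' @param nets An `individual_nets` collection.
#' @param path Output path.
#' @export
write_edge_table <- function(nets, path) {
  stopifnot(inherits(nets, "individual_nets"))
  df <- data.frame(node_a = nets$edges$a, node_b = nets$edges$b,
                   nets$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A validated configuration list; see [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Build a validated run configuration
#'
#' @param modalities Named list of feature-matrix file paths (train).
#' @param modalities_test Named list of test feature-matrix paths (optional).
#' @param labels Path to the label table.
#' @param level One of `"nodes"`, `"edges"`, `"nodes_and_edges"`.
#' @param node_similarity One of `"affinity"`, `"gaussian"`, `"spearman"`.
#' @param edge_method One of `"node_product"`, `"lioness"`.
#' @param fusion One of `"none"`, `"early"`, `"intermediate_average"`,
#'   `"intermediate_snf"`, `"late"`.
#' @param n_nodes_grid,t_edge_grid Selection grids.
#' @param c_grid SVM cost grid.
#' @param folds Cross-validation folds.
#' @param seed Master integer seed; every random substream derives from it.
#' @param out_dir Output directory.
#' @return Configuration list of class `"ppn_config"`.
#' @export
run_config <- function(modalities = NULL, modalities_test = NULL,
                       labels = NULL,
                       level = c("nodes", "edges", "nodes_and_edges"),
                       node_similarity = c("spearman", "affinity", "gaussian"),
                       edge_method = c("node_product", "lioness"),
                       fusion = c("none", "early", "intermediate_average",
                                  "intermediate_snf", "late"),
                       n_nodes_grid = seq(100, 1400, by = 100),
                       t_edge_grid = c(0.25, 0.5, 0.75),
                       c_grid = 10^(1:5), folds = 5, seed = 1,
                       out_dir = NULL) {
  level <- match.arg(level)
  node_similarity <- match.arg(node_similarity)
  edge_method <- match.arg(edge_method)
  fusion <- match.arg(fusion)
  for (p in c(unlist(modalities), unlist(modalities_test), labels))
    if (!is.null(p) && !file.exists(p)) stop2("configured file not found: ", p)
  if (length(n_nodes_grid) == 0 || length(t_edge_grid) == 0 ||
      length(c_grid) == 0) stop2("selection/C grids must be non-empty")
  if (length(seed) != 1 || is.na(seed) || seed != round(seed))
    stop2("seed must be a single integer")
  structure(list(modalities = modalities, modalities_test = modalities_test,
                 labels = labels, level = level,
                 node_similarity = node_similarity, edge_method = edge_method,
                 fusion = fusion, n_nodes_grid = n_nodes_grid,
                 t_edge_grid = t_edge_grid, c_grid = c_grid, folds = folds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "ppn_config")
}

#' Write a JSON run log
#' @param info Named list of run metadata/results.
#' @param path Output path.
#' @export
write_run_log <- function(info, path) {
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
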