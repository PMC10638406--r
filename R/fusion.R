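#' Early fusion: feature-level concatenation of modalities
#'
#' Optionally applies per-modality top-variance node selection first, then
#' concatenates columns. Feature IDs get a `modality:` prefix so provenance
#' survives concatenation, and downstream edge selection may pair features
#' across modalities.
#'
#' @param matrices Named list of feature matrices over identical samples.
#' @param n_nodes Optional named vector/list: per-modality number of nodes
#'   to keep before concatenation.
#' @return A single feature matrix tagged `"early"`.
#' @export
early_fusion <- function(matrices, n_nodes = NULL) {
  if (length(matrices) == 0) stop2("no matrices supplied")
  if (is.null(names(matrices)))
    names(matrices) <- paste0("mod", seq_along(matrices))
  ids <- rownames(matrices[[1]])
  for (nm in names(matrices)) {
    diff <- c(setdiff(ids, rownames(matrices[[nm]])),
              setdiff(rownames(matrices[[nm]]), ids))
    if (length(diff))
      stop2("sample sets differ across modalities; mismatched IDs: ",
            paste(utils::head(diff, 5), collapse = ", "))
  }
  blocks <- lapply(names(matrices), function(nm) {
    m <- matrices[[nm]][ids, , drop = FALSE]
    if (!is.null(n_nodes) && !is.null(n_nodes[[nm]]))
      m <- m[, select_top_nodes(m, n_nodes[[nm]]), drop = FALSE]
    colnames(m) <- paste(nm, colnames(m), sep = ":")
    m
  })
  feature_matrix(do.call(cbind, blocks), modality = "early")
}

#' Intermediate fusion by averaging PPNs
#'
#' Elementwise mean of two or more normalized PPNs over identical samples.
#'
#' @param ppns List of normalized [new_ppn()] objects.
#' @return A [new_ppn()] of kind `"fused"`.
#' @export
intermediate_average <- function(ppns) {
  if (length(ppns) < 2) stop2("intermediate fusion needs >= 2 PPNs")
  ref <- ppns[[1]]
  for (p in ppns) {
    stopifnot(inherits(p, "ppn"))
    if (!p$normalized) stop2("average PPNs after normalize_ppn")
    if (!identical(dimnames(p$train), dimnames(ref$train)))
      stop2("PPNs cover different train samples")
    if (!identical(is.null(p$test), is.null(ref$test)) ||
        (!is.null(p$test) && !identical(dimnames(p$test), dimnames(ref$test))))
      stop2("PPNs cover different test samples")
  }
  train <- Reduce(`+`, lapply(ppns, `[[`, "train")) / length(ppns)
  test <- self <- NULL
  if (!is.null(ref$test)) {
    test <- Reduce(`+`, lapply(ppns, `[[`, "test")) / length(ppns)
    self <- Reduce(`+`, lapply(ppns, `[[`, "self_test")) / length(ppns)
  }
  new_ppn(train, test, self, kind = "fused", normalized = TRUE)
}

# Full-kernel row normalization with the 1/2-diagonal convention:
# P(i,j) = W(i,j) / (2 * sum_{k != i} W(i,k)), P(i,i) = 1/2.
snf_full_kernel <- function(w) {
  rs <- rowSums(w) - diag(w)
  rs[rs == 0] <- .Machine$double.eps
  p <- w / (2 * rs)
  diag(p) <- 0.5
  p
}

# Sparse KNN kernel: keep each row's K most similar neighbours (self
# excluded), row-normalized.
snf_knn_kernel <- function(w, K) {
  n <- nrow(w)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    ord <- order(w[i, -i], decreasing = TRUE)
    nb <- seq_len(n)[-i][ord[seq_len(K)]]
    s[i, nb] <- w[i, nb] / sum(w[i, nb])
  }
  s
}

#' Similarity Network Fusion
#'
#' Iterative cross-diffusion of two or more square similarity matrices
#' over the same samples: each view's full kernel is updated through its
#' sparse K-nearest-neighbour kernel and the average of the other views,
#' `P_v <- S_v %*% mean(P_w, w != v) %*% t(S_v)`, with renormalization and
#' symmetrization each step. The fused network is the mean of the final
#' per-view kernels.
#'
#' @param ppns List of >= 2 square similarity matrices (or [new_ppn()]
#'   objects, whose train blocks are used) with identical sample IDs.
#' @param K Neighbourhood size of the sparse kernel (default 20).
#' @param iterations Maximum diffusion steps (default 20); iteration stops
#'   early when the fused matrix changes by less than `tol` in max norm.
#' @param tol Early-stopping tolerance (default 1e-8).
#' @return Fused square similarity matrix.
#' @export
snf_fuse <- function(ppns, K = 20, iterations = 20, tol = 1e-8) {
  ws <- lapply(ppns, function(p) if (inherits(p, "ppn")) p$train else p)
  if (length(ws) < 2) stop2("SNF needs >= 2 similarity matrices")
  n <- nrow(ws[[1]])
  for (w in ws) {
    if (!is.matrix(w) || nrow(w) != ncol(w))
      stop2("SNF inputs must be square matrices")
    if (nrow(w) != n || !identical(dimnames(w), dimnames(ws[[1]])))
      stop2("SNF inputs must share one sample set")
  }
  if (K >= n) stop2("K must be smaller than the number of samples")
  ps <- lapply(ws, function(w) snf_full_kernel((w + t(w)) / 2))
  ss <- lapply(ws, function(w) snf_knn_kernel((w + t(w)) / 2, K))
  fused_prev <- Reduce(`+`, ps) / length(ps)
  for (it in seq_len(iterations)) {
    ps_next <- lapply(seq_along(ps), function(v) {
      others <- Reduce(`+`, ps[-v]) / (length(ps) - 1)
      p <- ss[[v]] %*% others %*% t(ss[[v]])
      snf_full_kernel((p + t(p)) / 2)
    })
    ps <- ps_next
    fused <- Reduce(`+`, ps) / length(ps)
    if (max(abs(fused - fused_prev)) < tol) break
    fused_prev <- fused
  }
  fused <- Reduce(`+`, ps) / length(ps)
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(ws[[1]])
  fused
}
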