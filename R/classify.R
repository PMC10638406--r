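#' Clip a symmetric similarity matrix to positive semidefinite
#'
#' Eigenvalues below zero are set to zero and the matrix is rebuilt.
#' Already-PSD matrices pass through unchanged (up to numerical noise), so
#' the repair is idempotent.
#'
#' @param k Symmetric numeric matrix.
#' @param tol Eigenvalues below `-tol * max(|lambda|)` trigger the rebuild.
#' @return PSD matrix with the input's dimnames.
#' @export
psd_clip <- function(k, tol = 1e-10) {
  k <- (k + t(k)) / 2
  e <- eigen(k, symmetric = TRUE)
  if (min(e$values) >= -tol * max(abs(e$values), 1))
    return(k)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(k)
  out
}

# Fit a C-SVC on a precomputed similarity matrix (internal, fixed C).
svm_fit_kernel <- function(k_train, labels, C, psd_repair = TRUE) {
  labels <- labels[rownames(k_train)]
  if (any(is.na(labels))) stop2("labels missing for some training samples")
  y <- factor(labels)
  if (nlevels(y) < 2) stop2("training labels contain a single class")
  k <- if (psd_repair) psd_clip(k_train) else k_train
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(k), y, type = "C-svc",
                       C = C, kernel = "matrix")
  structure(list(fit = fit, train_ids = rownames(k_train), C = C,
                 levels = levels(y), psd_repair = psd_repair),
            class = "ppn_svm")
}

#' @export
print.ppn_svm <- function(x, ...) {
  cat("Precomputed-similarity SVM: ", length(x$train_ids),
      " train samples, C = ", x$C, ", classes: ",
      paste(x$levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Train a similarity-matrix SVM with cost selection
#'
#' Fits a C-SVC directly on a normalized square Person-to-Person Network.
#' The similarity matrix is first repaired to positive semidefinite by
#' eigenvalue clipping (Spearman or averaged PPNs can be indefinite). The
#' cost C is selected from `c_grid` either by stratified k-fold
#' cross-validated macro F1 inside the training set (default) or by
#' training-set fit; ties go to the smallest C.
#'
#' @param ppn_train Square normalized similarity matrix (or a [new_ppn()],
#'   whose train block is used).
#' @param labels Named label vector covering the training samples.
#' @param c_grid Candidate costs, default `10^(1:5)`.
#' @param folds CV folds for cost selection.
#' @param seed Integer seed for the fold split.
#' @param c_select `"cv"` (default) or `"train"`.
#' @param psd_repair Apply the PSD clip (default `TRUE`).
#' @return A `"ppn_svm"` model storing the fit, chosen C and train IDs.
#' @export
train_svm <- function(ppn_train, labels, c_grid = 10^(1:5), folds = 5,
                      seed = 1, c_select = c("cv", "train"),
                      psd_repair = TRUE) {
  c_select <- match.arg(c_select)
  if (inherits(ppn_train, "ppn")) ppn_train <- ppn_train$train
  labels <- labels[rownames(ppn_train)]
  if (any(is.na(labels))) stop2("labels missing for some training samples")
  c_grid <- sort(c_grid)
  if (length(c_grid) == 1) {
    chosen <- c_grid
  } else if (c_select == "train") {
    # ascending C with exact early stop: once the training macro F1 hits 1,
    # no larger C can win under the smallest-C tie-break
    best_score <- -Inf; best_model <- NULL; chosen <- c_grid[1]
    for (C in c_grid) {
      model <- svm_fit_kernel(ppn_train, labels, C, psd_repair)
      score <- macro_f1(labels, predict_ppn(model, ppn_train))$macro
      if (score > best_score) {
        best_score <- score; best_model <- model; chosen <- C
      }
      if (best_score >= 1) break
    }
    best_model$c_grid <- c_grid
    return(best_model)
  } else {
    fold_id <- stratified_folds(labels, folds, derive_seed(seed, "svm_cv"))
    scores <- vapply(c_grid, function(C) {
      mean(vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        if (length(unique(labels[tr])) < 2 || !any(!tr)) return(NA_real_)
        model <- svm_fit_kernel(ppn_train[tr, tr, drop = FALSE],
                                labels[tr], C, psd_repair)
        pred <- predict_ppn(model, ppn_train[!tr, tr, drop = FALSE])
        macro_f1(labels[!tr], pred)$macro
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    chosen <- c_grid[which.max(scores)]
  }
  model <- svm_fit_kernel(ppn_train, labels, chosen, psd_repair)
  model$c_grid <- c_grid
  model
}

#' Predict labels from test-to-train similarities
#'
#' @param model A `"ppn_svm"` from [train_svm()].
#' @param ppn_test Rectangular test-by-train similarity matrix (or a
#'   [new_ppn()] with a test block), normalized with the same scheme as
#'   training. Columns are matched to training samples by ID.
#' @return Named character vector of predicted labels.
#' @export
predict_ppn <- function(model, ppn_test) {
  stopifnot(inherits(model, "ppn_svm"))
  if (inherits(ppn_test, "ppn")) ppn_test <- ppn_test$test
  missing <- setdiff(model$train_ids, colnames(ppn_test))
  if (length(missing))
    stop2("test PPN lacks column(s) for training sample(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  k <- ppn_test[, model$train_ids, drop = FALSE]
  sv <- kernlab::SVindex(model$fit)
  pred <- kernlab::predict(
    model$fit, kernlab::as.kernelMatrix(k[, sv, drop = FALSE]))
  stats::setNames(as.character(pred), rownames(ppn_test))
}

#' Macro F1 score and per-class breakdown
#'
#' Per-class F1 is `2 TP / (2 TP + FP + FN)`, set to 0 when the class has
#' no true and no predicted positives; the macro score is the unweighted
#' mean over the label set.
#'
#' @param truth Named (or aligned) true labels.
#' @param predicted Predicted labels; matched to `truth` by name when both
#'   are named.
#' @param label_set Classes to average over; defaults to the classes
#'   present in `truth`.
#' @return List with `macro`, `per_class` (named F1 vector) and
#'   `confusion` (truth x predicted table).
#' @export
macro_f1 <- function(truth, predicted, label_set = NULL) {
  if (!is.null(names(truth)) && !is.null(names(predicted))) {
    if (!setequal(names(truth), names(predicted)))
      stop2("truth and predicted cover different samples")
    predicted <- predicted[names(truth)]
  } else if (length(truth) != length(predicted)) {
    stop2("truth and predicted differ in length")
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  label_set <- label_set %||% sort(unique(truth))
  per_class <- vapply(label_set, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  lv <- sort(unique(c(truth, predicted, label_set)))
  confusion <- table(truth = factor(truth, lv),
                     predicted = factor(predicted, lv))
  list(macro = mean(per_class), per_class = per_class,
       confusion = confusion)
}

#' Late fusion by majority vote
#'
#' Per-sample modal label over two or more prediction sets; exact ties are
#' broken uniformly at random from the seeded stream. Also reports each
#' prediction set's contribution: how often it agrees with the final call,
#' tied samples excluded.
#'
#' @param prediction_sets Named list of named label vectors over the same
#'   samples.
#' @param seed Integer seed for tie-breaking.
#' @return List with `labels` (final predictions), `contribution`
#'   (per-set agreement frequency in percent) and `tied` (sample IDs whose
#'   vote was tied).
#' @export
late_fusion_majority <- function(prediction_sets, seed = 1) {
  if (length(prediction_sets) < 2)
    stop2("majority vote needs at least 2 prediction sets")
  ids <- names(prediction_sets[[1]])
  for (p in prediction_sets)
    if (!setequal(names(p), ids))
      stop2("prediction sets cover different samples")
  votes <- vapply(prediction_sets, function(p) p[ids], character(length(ids)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1,
                                           dimnames = list(ids, NULL))
  final <- character(length(ids))
  tied <- logical(length(ids))
  with_seed(derive_seed(seed, "tie_break"), {
    for (i in seq_along(ids)) {
      tab <- table(votes[i, ])
      top <- names(tab)[tab == max(tab)]
      tied[i] <- length(top) > 1
      final[i] <- if (tied[i]) top[sample.int(length(top), 1)] else top
    }
  })
  names(final) <- ids
  contribution <- vapply(seq_along(prediction_sets), function(j) {
    keep <- !tied
    if (!any(keep)) return(NA_real_)
    100 * mean(votes[keep, j] == final[keep])
  }, numeric(1))
  names(contribution) <- names(prediction_sets) %||%
    paste0("set", seq_along(prediction_sets))
  list(labels = final, contribution = contribution, tied = ids[tied])
}
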