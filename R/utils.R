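# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic substream seed: one master seed, named consumers.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop2(what, " contains non-finite values")
  invisible(x)
}

# Stratified fold assignment: preserves class proportions within +/- 1
# sample per fold. Returns an integer fold id per sample.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

upper_pairs <- function(ids) {
  p <- length(ids)
  if (p < 2) stop2("need at least 2 features to enumerate edges")
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- sequence((p - 1L):1L) + i
  data.frame(a = ids[i], b = ids[j], stringsAsFactors = FALSE)
}
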