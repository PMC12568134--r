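#' SMOTE: synthetic minority oversampling
#'
#' Generates `n_new` synthetic rows from a minority-class feature matrix.
#' Each synthetic row is `p + lambda * (q - p)` with `p` a uniformly chosen
#' minority row, `q` one of `p`'s `k` nearest minority neighbours
#' (Euclidean distance), and `lambda ~ U[0, 1]` — i.e. a random point on
#' the segment between two nearby minority examples. Deterministic under a
#' fixed seed. If the nearest neighbour coincides with its parent the
#' synthetic point equals the parent (allowed degenerate case).
#'
#' @param minority numeric matrix or data frame of minority-class rows
#'   (>= 2 rows).
#' @param n_new number of synthetic rows to generate (>= 0).
#' @param k neighbour count; clamped to `nrow(minority) - 1` with a
#'   warning if larger.
#' @param seed RNG seed.
#' @return a numeric matrix with `n_new` rows and the input's columns.
#' @export
smote_sample <- function(minority, n_new, k = 5, seed = 1) {
  X <- as.matrix(minority)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 2L) abort_usage("SMOTE needs at least 2 minority rows")
  if (n_new < 0) abort_usage("n_new must be >= 0")
  if (k > n - 1L) {
    warning(sprintf("k = %d exceeds minority size - 1; clamped to %d", k, n - 1L))
    k <- n - 1L
  }
  if (n_new == 0L) return(X[0L, , drop = FALSE])
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  # k nearest minority neighbours of each row, ties by smallest index
  nn <- do.call(rbind, lapply(seq_len(n), function(i) {
    order(D[i, ], seq_len(n))[seq_len(k)]
  }))
  withr::with_seed(seed, {
    p_idx <- sample.int(n, n_new, replace = TRUE)
    q_col <- sample.int(k, n_new, replace = TRUE)
    lambda <- stats::runif(n_new)
  })
  q_idx <- nn[cbind(p_idx, q_col)]
  P <- X[p_idx, , drop = FALSE]
  Q <- X[q_idx, , drop = FALSE]
  out <- P + lambda * (Q - P)
  dimnames(out) <- list(NULL, colnames(X))
  out
}

#' Balance a training feature table by SMOTE
#'
#' Oversamples every non-majority class up to the majority count. Original
#' rows are preserved first (unchanged, in order); synthetic rows follow
#' with `subject_id = "synthetic"` so leakage audits can recognise them.
#' Intended for training folds only — synthetic rows must never reach a
#' test fold, which [run_cv()] guarantees by balancing after the split.
#'
#' @param features a feature tibble with a `label` column (and optionally
#'   `subject_id`); all other columns are treated per [feature_cols()].
#' @param k SMOTE neighbour count (default 5, the classic choice).
#' @param seed RNG seed.
#' @return a feature tibble in which every class count equals the majority
#'   count.
#' @export
balance_training_set <- function(features, k = 5, seed = 1) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  counts <- table(features$label)
  if (length(counts) < 2L) abort_usage("balancing needs at least two classes")
  target <- max(counts)
  fcols <- feature_cols(features)
  synth <- purrr::imap(as.list(counts), function(cnt, cls) {
    need <- target - cnt
    if (need == 0L) return(NULL)
    rows <- features[features$label == cls, fcols, drop = FALSE]
    new <- smote_sample(rows, n_new = need, k = k,
                        seed = derive_seed(seed, match(cls, names(counts))))
    out <- tibble::as_tibble(as.data.frame(new))
    out$label <- cls
    if ("subject_id" %in% names(features)) out$subject_id <- "synthetic"
    out
  })
  dplyr::bind_rows(c(list(features), synth))
}
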