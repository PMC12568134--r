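#' Sampling Shapley attributions for one instance
#'
#' Model-agnostic permutation-sampling estimate of Shapley values with
#' background imputation: for each sampled permutation a background row is
#' drawn, features are switched one by one (in permutation order) from the
#' background's values to the instance's values, and each feature is
#' credited with the score increment it causes. Averaging over
#' permutations yields `phi`; the Monte-Carlo standard error per feature
#' is reported alongside. By construction the attributions satisfy
#' efficiency up to Monte-Carlo error: `sum(phi)` estimates
#' `f(instance) - base_value`, where `base_value` is the mean score over
#' the background. Deterministic under a fixed seed.
#'
#' @param model_fn a deterministic score function mapping a matrix / data
#'   frame of feature rows to a numeric vector (see [score_function()]).
#' @param instance a single feature row (named numeric vector or one-row
#'   data frame).
#' @param background feature rows used for imputation (matrix or data
#'   frame, non-empty).
#' @param n_perm number of sampled permutations (>= 1; default 200).
#' @param seed RNG seed.
#' @return an `attribution` object: tibble `phi` with columns `feature`,
#'   `value`, `phi`, `mc_error`, plus `base_value`, `fx`, `n_perm`,
#'   `seed`.
#' @export
shapley_attributions <- function(model_fn, instance, background,
                                 n_perm = 200, seed = 1) {
  if (n_perm < 1) abort_usage("n_perm must be >= 1")
  B <- as.matrix(as.data.frame(background))
  storage.mode(B) <- "double"
  if (nrow(B) == 0L) abort_usage("background must be non-empty")
  x <- if (is.data.frame(instance) || is.matrix(instance)) {
    unlist(as.data.frame(instance)[1, , drop = FALSE])
  } else {
    instance
  }
  if (!identical(names(x), colnames(B))) {
    x <- x[colnames(B)]
    if (anyNA(x)) abort_usage("instance and background feature names disagree")
  }
  d <- length(x)
  feat <- colnames(B)
  base_scores <- model_fn(B)
  base_value <- mean(base_scores)
  fx <- as.numeric(model_fn(matrix(x, 1L, dimnames = list(NULL, feat))))

  inc <- matrix(0, n_perm, d, dimnames = list(NULL, feat))
  withr::with_seed(seed, {
    b_idx <- sample.int(nrow(B), n_perm, replace = TRUE)
    perms <- lapply(seq_len(n_perm), function(i) sample.int(d))
  })
  for (p in seq_len(n_perm)) {
    pi_p <- perms[[p]]
    # rows 1..d+1: background row progressively overwritten with x in pi order
    Zp <- matrix(rep(B[b_idx[p], ], d + 1L), d + 1L, d, byrow = TRUE,
                 dimnames = list(NULL, feat))
    for (j in seq_len(d)) {
      Zp[(j + 1L):(d + 1L), pi_p[j]] <- x[pi_p[j]]
    }
    scores <- model_fn(Zp)
    inc[p, pi_p] <- diff(scores)
  }
  phi <- colMeans(inc)
  mc_error <- apply(inc, 2L, stats::sd) / sqrt(n_perm)
  structure(list(
    phi = tibble::tibble(feature = feat, value = as.numeric(x),
                         phi = as.numeric(phi), mc_error = as.numeric(mc_error)),
    base_value = base_value, fx = fx, n_perm = n_perm, seed = seed
  ), class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  gap <- abs(sum(x$phi$phi) - (x$fx - x$base_value))
  cat(sprintf("<attribution> %d features, %d permutations; f(x) = %.4f, base = %.4f, efficiency gap = %.2e\n",
              nrow(x$phi), x$n_perm, x$fx, x$base_value, gap))
  print(dplyr::arrange(x$phi, dplyr::desc(abs(.data$phi))), n = 5)
  invisible(x)
}

#' Global feature importance from a set of attributions
#'
#' Ranks features by mean absolute attribution over the explained
#' instances (the ordering a beeswarm display sorts by). Ties are broken
#' by the canonical feature order of the first attribution.
#'
#' @param attributions a list of `attribution` objects (non-empty, with
#'   identical feature sets).
#' @return a tibble with columns `rank`, `feature`, `mean_abs_phi`.
#' @export
global_importance <- function(attributions) {
  if (inherits(attributions, "attribution")) attributions <- list(attributions)
  if (length(attributions) == 0L) abort_usage("need at least one attribution")
  feat <- attributions[[1]]$phi$feature
  mat <- vapply(attributions, function(a) {
    if (!identical(a$phi$feature, feat)) abort_usage("attribution feature sets disagree")
    abs(a$phi$phi)
  }, numeric(length(feat)))
  mean_abs <- rowMeans(matrix(mat, nrow = length(feat)))
  ord <- order(-mean_abs, seq_along(feat))
  tibble::tibble(rank = seq_along(feat), feature = feat[ord],
                 mean_abs_phi = mean_abs[ord])
}

#' Explain a set of instances with a fitted detector
#'
#' Convenience wrapper: attributes the detector's score (positive-class
#' vote fraction for KNN, signed decision value for SVM) for each row of
#' `instances` against a seeded background subsample of `background`.
#'
#' @param model a `fall_detector`.
#' @param instances feature tibble of rows to explain.
#' @param background feature tibble (typically the training set); a
#'   subsample of `background_size` rows is used for imputation.
#' @param n_perm permutations per instance.
#' @param background_size background subsample size (default 100).
#' @param seed RNG seed.
#' @return a list with `attributions` (one per instance), `long` (tidy
#'   long tibble: `instance`, `feature`, `value`, `phi`, `mc_error`), and
#'   `importance` (from [global_importance()]).
#' @export
explain_detector <- function(model, instances, background, n_perm = 100,
                             background_size = 100, seed = 1) {
  stopifnot(inherits(model, "fall_detector"))
  fcols <- model$feature_names
  bg <- as.data.frame(background)[fcols]
  if (nrow(bg) > background_size) {
    keep <- withr::with_seed(derive_seed(seed, 7L),
                             sample.int(nrow(bg), background_size))
    bg <- bg[keep, , drop = FALSE]
  }
  fn <- score_function(model)
  inst <- as.data.frame(instances)[fcols]
  atts <- lapply(seq_len(nrow(inst)), function(i) {
    shapley_attributions(fn, inst[i, , drop = FALSE], bg, n_perm = n_perm,
                         seed = derive_seed(seed, 100L + i))
  })
  long <- dplyr::bind_rows(lapply(seq_along(atts), function(i) {
    dplyr::mutate(atts[[i]]$phi, instance = i, .before = 1)
  }))
  list(attributions = atts, long = long, importance = global_importance(atts))
}
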