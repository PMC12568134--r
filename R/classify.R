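#' Detector model specification
#'
#' The two detectors share one contract: z-score standardization fitted on
#' the training rows (on by default — the feature bank mixes g-scale means
#' with dimensionless kurtosis, and nearest-neighbour distances are
#' scale-sensitive), then either a k-nearest-neighbour vote (default
#' k = 1) or an RBF-kernel SVM with `gamma = 1 / (n_features * Var(X))`
#' computed on the (standardized) training matrix and box penalty `C`.
#'
#' @param kind `"knn"` or `"svm"`.
#' @param k neighbour count for knn (default 1).
#' @param C SVM box penalty (default 1).
#' @param standardize fit and apply per-feature z-scoring (default `TRUE`).
#' @return a `model_spec` object.
#' @export
model_spec <- function(kind = c("knn", "svm"), k = 1, C = 1, standardize = TRUE) {
  kind <- match.arg(kind)
  if (k < 1 || k != round(k)) abort_usage("k must be an integer >= 1")
  if (C <= 0) abort_usage("C must be > 0")
  structure(list(kind = kind, k = as.integer(k), C = C,
                 gamma_mode = "scale", standardize = isTRUE(standardize)),
            class = "model_spec")
}

#' Fit a fall detector
#'
#' Computes the standardizer (per-feature mean and population sd; sd of 0
#' replaced by 1) on the training rows only, then fits the classifier on
#' the standardized matrix. Deterministic given the seed.
#'
#' @param features a feature tibble with a `label` column.
#' @param spec a [model_spec()].
#' @param positive the positive (fall) class label, default `"FALL"`.
#' @param seed RNG seed (recorded in the fingerprint; both detectors are
#'   deterministic fits).
#' @return a `fall_detector` object.
#' @export
fit_detector <- function(features, spec = model_spec(), positive = "FALL", seed = 1) {
  stopifnot(inherits(spec, "model_spec"), "label" %in% names(features))
  fcols <- feature_cols(features)
  X <- as.matrix(features[fcols])
  storage.mode(X) <- "double"
  y <- as.character(features$label)
  if (length(unique(y)) < 2L) abort_usage("training data must contain >= 2 classes")
  bad <- colnames(X)[colSums(!is.finite(X)) > 0]
  if (length(bad) > 0) abort_usage(sprintf("non-finite feature values in column %s", bad[1]))

  center <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2L, center)^2))
  sdev[sdev == 0] <- 1
  if (!spec$standardize) {
    center <- rep(0, ncol(X)); sdev <- rep(1, ncol(X))
  }
  Z <- sweep(sweep(X, 2L, center), 2L, sdev, "/")

  gamma <- 1 / (ncol(Z) * stats::var(as.vector(Z)) * (length(Z) - 1) / length(Z))
  fit <- NULL
  if (spec$kind == "svm") {
    yf <- factor(y)
    fit <- withr::with_seed(derive_seed(seed, 1L), {
      e1071::svm(x = Z, y = yf, type = "C-classification", kernel = "radial",
                 gamma = gamma, cost = spec$C, scale = FALSE)
    })
  }
  structure(list(
    spec = spec, center = center, scale = sdev, gamma = gamma,
    train_x = if (spec$kind == "knn") Z else NULL,
    train_y = if (spec$kind == "knn") y else NULL,
    svm_fit = fit,
    classes = sort(unique(y)), positive = positive,
    feature_names = fcols,
    fingerprint = list(n_rows = nrow(Z), n_features = ncol(Z), seed = seed)
  ), class = "fall_detector")
}

#' @export
print.fall_detector <- function(x, ...) {
  cat(sprintf("<fall_detector> %s on %d x %d training rows (classes: %s)\n",
              x$spec$kind, x$fingerprint$n_rows, x$fingerprint$n_features,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

standardize_rows <- function(object, newdata) {
  X <- as.matrix(as.data.frame(newdata)[object$feature_names])
  storage.mode(X) <- "double"
  sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
}

# squared Euclidean distances between rows of A (m x d) and B (n x d)
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Predict labels with a fitted detector
#'
#' KNN uses Euclidean distance on standardized features; neighbour ties at
#' equal distance are broken by the smallest training-row index, and a
#' tied vote (impossible at k = 1) falls to the class of the nearest
#' neighbour among the tied classes.
#'
#' @param object a `fall_detector`.
#' @param newdata a feature tibble or matrix with the training feature
#'   columns.
#' @param ... unused.
#' @return a character vector of predicted labels, one per row.
#' @export
predict.fall_detector <- function(object, newdata, ...) {
  if (NROW(newdata) == 0L) return(character())
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0) {
    abort_usage(sprintf("newdata lacks %d training feature column(s), e.g. %s",
                        length(missing), missing[1]))
  }
  Z <- standardize_rows(object, newdata)
  if (object$spec$kind == "svm") {
    return(as.character(stats::predict(object$svm_fit, Z)))
  }
  knn_predict(object$train_x, object$train_y, Z, object$spec$k)
}

knn_predict <- function(train_x, train_y, Z, k) {
  d2 <- cross_dist2(Z, train_x)
  apply(d2, 1L, function(d) {
    nn <- order(d, seq_along(d))[seq_len(k)]   # distance ties -> smallest index
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    train_y[nn][train_y[nn] %in% top][1L]      # vote tie -> nearest tied class
  })
}

#' Continuous detector scores for attribution
#'
#' Returns a vectorized score function mapping feature rows to a single
#' number increasing with fall likelihood: for KNN the fraction of the k
#' nearest training rows labeled positive (0/1 at k = 1); for SVM the
#' signed decision value, oriented so positive means the positive class.
#'
#' @param object a `fall_detector`.
#' @return a function `(rows) -> numeric`.
#' @export
score_function <- function(object) {
  stopifnot(inherits(object, "fall_detector"))
  if (object$spec$kind == "knn") {
    function(rows) {
      Z <- standardize_rows(object, rows)
      d2 <- cross_dist2(Z, object$train_x)
      apply(d2, 1L, function(d) {
        nn <- order(d, seq_along(d))[seq_len(object$spec$k)]
        mean(object$train_y[nn] == object$positive)
      })
    }
  } else {
    function(rows) {
      Z <- standardize_rows(object, rows)
      pr <- stats::predict(object$svm_fit, Z, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 labels the column "A/B": decision value is positive for class A
      cn <- colnames(dv)[1]
      first <- strsplit(cn, "/", fixed = TRUE)[[1]][1]
      sign <- if (identical(first, object$positive)) 1 else -1
      sign * as.numeric(dv[, 1])
    }
  }
}

#' Save / load a fitted detector
#'
#' Single-file archive (RDS) holding the spec, standardizer and model
#' state, with a format version.
#'
#' @param object a `fall_detector`.
#' @param path destination file.
#' @return `load_detector()` returns the detector; `save_detector()` the
#'   path, invisibly.
#' @export
save_detector <- function(object, path) {
  stopifnot(inherits(object, "fall_detector"))
  saveRDS(list(format = "fallwin-detector-1", model = object), path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "fallwin-detector-1")) {
    abort_data("not a fallwin detector archive")
  }
  obj$model
}
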