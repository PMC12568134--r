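#' Tidy a cross-validation result
#'
#' One row per fold with all metrics, in broom style.
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return a tibble of per-fold metrics.
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::relocate(x$folds, "fold")
}

#' Glance at a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return a one-row tibble: model kind, fold mode, fold count, and the
#'   mean of each metric over folds.
#' @export
glance.cv_result <- function(x, ...) {
  means <- stats::setNames(as.list(x$summary$mean), paste0("mean_", x$summary$metric))
  dplyr::bind_cols(
    tibble::tibble(kind = x$spec$kind, mode = x$mode, n_folds = nrow(x$folds),
                   smote = x$smote),
    tibble::as_tibble(means)
  )
}

#' Tidy a streaming result
#'
#' @param x a `streaming_result`.
#' @param ... unused.
#' @return the per-window decision tibble.
#' @export
tidy.streaming_result <- function(x, ...) x$decisions

#' Glance at a streaming result
#'
#' @param x a `streaming_result`.
#' @param ... unused.
#' @return a one-row tibble of counts and rates.
#' @export
glance.streaming_result <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$decisions), n_alarms = length(x$alarms),
    event_tp = x$event_tp, event_fn = x$event_fn,
    window_tn = x$window_tn, window_fp = x$window_fp,
    sensitivity = x$sensitivity, specificity = x$specificity,
    window_s = x$cfg$window_s, overlap = x$cfg$overlap
  )
}

#' Tidy a fitted detector
#'
#' @param x a `fall_detector`.
#' @param ... unused.
#' @return a tibble with one row per feature: standardizer center and
#'   scale.
#' @export
tidy.fall_detector <- function(x, ...) {
  tibble::tibble(feature = x$feature_names, center = unname(x$center),
                 scale = unname(x$scale))
}

#' Glance at a fitted detector
#'
#' @param x a `fall_detector`.
#' @param ... unused.
#' @return a one-row tibble: kind, hyperparameters, training shape.
#' @export
glance.fall_detector <- function(x, ...) {
  tibble::tibble(
    kind = x$spec$kind, k = x$spec$k, C = x$spec$C, gamma = x$gamma,
    standardize = x$spec$standardize,
    n_rows = x$fingerprint$n_rows, n_features = x$fingerprint$n_features,
    classes = paste(x$classes, collapse = ",")
  )
}

#' Tidy an attribution
#'
#' @param x an `attribution`.
#' @param ... unused.
#' @return the per-feature phi tibble.
#' @export
tidy.attribution <- function(x, ...) x$phi

#' Glance at an attribution
#'
#' @param x an `attribution`.
#' @param ... unused.
#' @return a one-row tibble: score at the instance, base value, summed
#'   phi, efficiency gap and aggregate Monte-Carlo error.
#' @export
glance.attribution <- function(x, ...) {
  tibble::tibble(
    fx = x$fx, base_value = x$base_value, sum_phi = sum(x$phi$phi),
    efficiency_gap = abs(sum(x$phi$phi) - (x$fx - x$base_value)),
    aggregate_mc_error = sqrt(sum(x$phi$mc_error^2)),
    n_perm = x$n_perm
  )
}
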