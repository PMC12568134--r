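#' Hyperparameter sweeps over the segmentation family
#'
#' Re-runs the full feature-extraction + cross-validation pipeline while
#' varying one segmentation hyperparameter: window length `n` (seconds),
#' sub-window overlap `o`, or sub-window count `m`. The classic grids are
#' `n` in 1..5, `o` in 0, 0.1, ..., 0.9 and `m` in 1..5. Returns one row
#' per grid point and fold, sufficient to draw metric-versus-parameter
#' curves. Invalid grid points (e.g. a hop rounding to zero samples) are
#' skipped with a message.
#'
#' @param events a single-event dataset tibble (see [gen_event_dataset()]).
#' @param axis `"n"`, `"o"` or `"m"`.
#' @param grid numeric vector of grid values; defaults to the classic grid
#'   for the axis.
#' @param base_scheme scheme whose other two parameters are held fixed.
#' @param spec a [model_spec()].
#' @param mode,k fold plan parameters (see [make_folds()]).
#' @param smote apply SMOTE in training folds.
#' @param seed root seed.
#' @return a tibble: `axis`, `value`, per-fold metric columns.
#' @export
run_sweep <- function(events, axis = c("n", "o", "m"), grid = NULL,
                      base_scheme = window_scheme(), spec = model_spec(),
                      mode = "kfold", k = 5, smote = TRUE, seed = 1) {
  axis <- match.arg(axis)
  grid <- grid %||% switch(axis, n = 1:5, o = seq(0, 0.9, by = 0.1), m = 1:5)
  out <- list()
  for (v in grid) {
    scheme <- tryCatch(switch(axis,
      n = window_scheme(v, base_scheme$m, base_scheme$o),
      o = window_scheme(base_scheme$n_s, base_scheme$m, v),
      m = window_scheme(base_scheme$n_s, v, base_scheme$o)
    ), error = function(e) NULL)
    if (is.null(scheme)) { message(sprintf("grid point %s = %g skipped (invalid scheme)", axis, v)); next }
    # anchor each window at the event start so window lengths up to the
    # trace duration are sweepable on fixed-length event recordings
    feats <- tryCatch({
      f <- dplyr::bind_rows(purrr::map(events$trace, window_features,
                                       scheme = scheme, start_sample = 0L))
      f$label <- events$label
      f$subject_id <- events$subject_id
      f
    }, error = function(e) NULL)
    if (is.null(feats)) { message(sprintf("grid point %s = %g skipped (extraction failed)", axis, v)); next }
    plan <- make_folds(feats, mode = mode, k = k, seed = derive_seed(seed, round(1000 * v)))
    cv <- run_cv(feats, plan, spec, smote = smote, seed = derive_seed(seed, round(2000 * v)))
    out[[length(out) + 1L]] <- dplyr::mutate(cv$folds, axis = axis, value = v, .before = 1)
  }
  dplyr::bind_rows(out)
}

#' Streaming overlap sweep
#'
#' Runs [streaming_evaluate()] over a grid of sliding-window overlaps
#' (classically 0.1 to 0.9 in steps of 0.1) on one or more annotated
#' recordings, pooling event and window counts per overlap.
#'
#' @param recordings a list of annotated [triaxial_trace()]s.
#' @param model a `fall_detector` (or oracle function, see
#'   [streaming_evaluate()]).
#' @param scheme the feature [window_scheme()].
#' @param grid overlap grid (default 0.1..0.9 by 0.1).
#' @param match_tolerance_s event-matching tolerance in seconds.
#' @param positive positive class label.
#' @return a tibble with one row per overlap: pooled `event_tp`,
#'   `event_fn`, `window_tn`, `window_fp`, `sensitivity`, `specificity`,
#'   `n_windows`.
#' @export
run_stream_sweep <- function(recordings, model, scheme = window_scheme(),
                             grid = seq(0.1, 0.9, by = 0.1),
                             match_tolerance_s = 3, positive = "FALL") {
  if (inherits(recordings, "triaxial_trace")) recordings <- list(recordings)
  rows <- lapply(grid, function(o) {
    cfg <- stream_config(window_s = scheme$n_s, overlap = o)
    res <- lapply(recordings, streaming_evaluate, model = model, scheme = scheme,
                  cfg = cfg, match_tolerance_s = match_tolerance_s,
                  positive = positive)
    tp <- sum(vapply(res, `[[`, numeric(1), "event_tp"))
    fn <- sum(vapply(res, `[[`, numeric(1), "event_fn"))
    tn <- sum(vapply(res, `[[`, numeric(1), "window_tn"))
    fp <- sum(vapply(res, `[[`, numeric(1), "window_fp"))
    tibble::tibble(
      overlap = o,
      event_tp = tp, event_fn = fn, window_tn = tn, window_fp = fp,
      sensitivity = safe_ratio(tp, tp + fn),
      specificity = safe_ratio(tn, tn + fp),
      n_windows = sum(vapply(res, function(r) nrow(r$decisions), numeric(1)))
    )
  })
  dplyr::bind_rows(rows)
}
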