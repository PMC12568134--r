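#' Streaming evaluation on an unsegmented continuous recording
#'
#' Slides windows over the trace (per `cfg`), extracts the sub-window
#' features of each window, and classifies them causally: the decision for
#' window `t` (0-based) uses only samples up to its end and is timestamped
#' at `t * H + W` seconds — the window end; positive decisions emit alarms
#' at those timestamps. Scoring is event-level for sensitivity and
#' window-level for specificity:
#'
#' * an annotated fall is an event true positive iff at least one
#'   positively-classified window overlaps its interval padded by
#'   `match_tolerance_s` on both sides (the OR rule), else an event false
#'   negative;
#' * windows that do not overlap any padded fall interval count as window
#'   true negatives (negative decision) or false positives (positive
#'   decision); windows inside the padded intervals are ambiguous and are
#'   excluded from specificity.
#'
#' @param trace an annotated [triaxial_trace()].
#' @param model a `fall_detector` trained on features of `scheme`, or a
#'   function `(features, windows) -> labels` (useful for oracle
#'   detectors in tests).
#' @param scheme the [window_scheme()] used for feature extraction; its
#'   window length must equal the streaming window length.
#' @param cfg a [stream_config()].
#' @param match_tolerance_s padding in seconds around each annotated fall
#'   (default 3, one window).
#' @param positive positive class label.
#' @return a `streaming_result` with per-window `decisions` (tibble:
#'   `window`, `start_s`, `end_s`, `label`, `decision_time_s`,
#'   `last_sample_used`), `alarms` (times in seconds), event counts
#'   `event_tp` / `event_fn`, window counts `window_tn` / `window_fp`,
#'   and `sensitivity` / `specificity`.
#' @export
streaming_evaluate <- function(trace, model, scheme = window_scheme(),
                               cfg = stream_config(overlap = 0.3),
                               match_tolerance_s = 3, positive = "FALL") {
  rate <- trace_rate(trace)
  if (round(cfg$window_s * rate) != round(scheme$n_s * rate)) {
    abort_usage("streaming window length must equal the feature scheme's window length")
  }
  windows <- slide_windows(trace, cfg)
  if (nrow(windows) == 0L) abort_usage("trace shorter than one streaming window")
  feats <- dplyr::bind_rows(purrr::map(windows$start_sample, function(s0) {
    window_features(trace, scheme, start_sample = s0)
  }))
  labels <- if (is.function(model)) {
    as.character(model(feats, windows))
  } else {
    if (!inherits(model, "fall_detector")) abort_usage("model must be a fall_detector or a function")
    predict(model, feats)
  }
  decisions <- dplyr::mutate(windows,
    label = labels,
    decision_time_s = .data$end_s,
    last_sample_used = .data$start_sample + .data$length_samples - 1L
  )
  alarms <- decisions$decision_time_s[decisions$label == positive]

  ann <- trace_annotations(trace)
  pad_lo <- ann$start_s - match_tolerance_s
  pad_hi <- ann$end_s + match_tolerance_s
  overlaps_event <- function(i) {
    decisions$start_s < pad_hi[i] & decisions$end_s > pad_lo[i]
  }
  event_hit <- vapply(seq_len(nrow(ann)), function(i) {
    any(overlaps_event(i) & decisions$label == positive)
  }, logical(1))
  in_any_pad <- rep(FALSE, nrow(decisions))
  for (i in seq_len(nrow(ann))) in_any_pad <- in_any_pad | overlaps_event(i)

  event_tp <- sum(event_hit); event_fn <- sum(!event_hit)
  neg <- decisions[!in_any_pad, , drop = FALSE]
  window_fp <- sum(neg$label == positive)
  window_tn <- sum(neg$label != positive)
  structure(list(
    decisions = decisions, alarms = alarms,
    event_tp = event_tp, event_fn = event_fn,
    window_tn = window_tn, window_fp = window_fp,
    sensitivity = if (event_tp + event_fn > 0) event_tp / (event_tp + event_fn) else NA_real_,
    specificity = safe_ratio(window_tn, window_tn + window_fp),
    cfg = cfg, scheme = scheme, match_tolerance_s = match_tolerance_s,
    positive = positive
  ), class = "streaming_result")
}

#' @export
print.streaming_result <- function(x, ...) {
  cat(sprintf(
    "<streaming_result> %d windows (W = %g s, overlap = %g), %d alarm(s)\n  events: %d TP / %d FN (sensitivity %.3f)  windows: %d TN / %d FP (specificity %.3f)\n",
    nrow(x$decisions), x$cfg$window_s, x$cfg$overlap, length(x$alarms),
    x$event_tp, x$event_fn, x$sensitivity, x$window_tn, x$window_fp, x$specificity))
  invisible(x)
}
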