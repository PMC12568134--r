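#' Per-axis statistics of one sub-window
#'
#' The seven per-axis statistics of the feature bank, computed with
#' population (1/n) moments: mean, median, standard deviation
#' `sqrt(mean((x - mu)^2))`, skewness `mean((x - mu)^3) / sd^3`, non-excess
#' kurtosis `mean((x - mu)^4) / sd^4`, maximum and minimum. On a constant
#' sequence (sd = 0) skewness and kurtosis are 0/0; the convention here is
#' 0 for both, which keeps the statistics shift-invariant.
#'
#' @param samples numeric vector of length >= 2 (acceleration in g).
#' @return a one-row tibble with columns `mean`, `median`, `sd`, `skew`,
#'   `kurt`, `max`, `min`.
#' @examples
#' axis_stats(c(1, 2, 3, 4))
#' @export
axis_stats <- function(samples) {
  if (length(samples) < 2L) abort_usage("axis_stats needs n >= 2 samples")
  assert_finite_numeric(samples, "samples")
  n <- length(samples)
  mu <- sum(samples) / n
  d <- samples - mu
  sdev <- sqrt(sum(d^2) / n)
  if (sdev > 0) {
    skew <- sum(d^3) / n / sdev^3
    kurt <- sum(d^4) / n / sdev^4
  } else {
    skew <- 0
    kurt <- 0
  }
  tibble::tibble(
    mean = mu, median = stats::median(samples), sd = sdev,
    skew = skew, kurt = kurt, max = max(samples), min = min(samples)
  )
}

#' Cross-axis range norm ("slope") of a sub-window
#'
#' `SL = sqrt((max_x - min_x)^2 + (max_y - min_y)^2 + (max_z - min_z)^2)`:
#' the Euclidean norm of the per-axis peak-to-peak ranges, a cheap proxy
#' for overall motion intensity within the sub-window.
#'
#' @param x,y,z numeric vectors (>= 1 sample each) for the three axes.
#' @return a single non-negative number in g.
#' @export
slope <- function(x, y, z) {
  if (length(x) < 1L) abort_usage("slope needs a non-empty sub-window")
  sqrt((max(x) - min(x))^2 + (max(y) - min(y))^2 + (max(z) - min(z))^2)
}

#' Canonical feature names for a scheme
#'
#' One block of 22 names per sub-window `s`: means `m_x{s}, m_y{s}, m_z{s}`,
#' medians `me_*`, standard deviations `sd_*`, skewness `sk_*`, kurtosis
#' `k_*`, maxima `max_*`, minima `min_*`, then the cross-axis range norm
#' `SLOP{s}`. Sub-window blocks are concatenated in time order, so the
#' default scheme yields 44 names ending in `SLOP2`.
#'
#' @param scheme a [window_scheme()].
#' @return a character vector of length `22 * m`.
#' @export
feature_names <- function(scheme = window_scheme()) {
  stopifnot(inherits(scheme, "window_scheme"))
  axes <- c("x", "y", "z")
  stats <- c("m", "me", "sd", "sk", "k", "max", "min")
  unlist(lapply(seq_len(scheme$m), function(s) {
    c(as.vector(t(outer(stats, axes, function(p, a) paste0(p, "_", a, s)))), paste0("SLOP", s))
  }), use.names = FALSE)
}

#' Extract the sub-window feature vector of one window
#'
#' For each sub-window of the scheme (in [subwindow_bounds()] order), the
#' seven per-axis statistics for x, y, z plus the cross-axis range norm:
#' 22 values per sub-window, `22 * m` in total (44 for the default
#' 3 s / 2 sub-window / 50% overlap scheme).
#'
#' @param trace a [triaxial_trace()].
#' @param scheme a [window_scheme()].
#' @param start_sample 0-based first sample of the window within `trace`
#'   (0 for single-event traces).
#' @return a one-row tibble with `22 * m` named feature columns, in
#'   [feature_names()] order.
#' @export
window_features <- function(trace, scheme = window_scheme(), start_sample = 0L) {
  rate <- trace_rate(trace)
  n_samp <- as.integer(round(scheme$n_s * rate))
  if (start_sample < 0L || start_sample + n_samp > nrow(trace)) {
    abort_usage("window extends beyond the trace")
  }
  bounds <- subwindow_bounds(scheme, rate)
  vals <- numeric(22L * scheme$m)
  pos <- 0L
  for (i in seq_len(nrow(bounds))) {
    idx <- (start_sample + bounds$start[i] + 1L):(start_sample + bounds$end[i])
    sx <- trace$x[idx]; sy <- trace$y[idx]; sz <- trace$z[idx]
    ax <- rbind(unlist(axis_stats(sx)), unlist(axis_stats(sy)), unlist(axis_stats(sz)))
    # stat-major within the sub-window: all means, all medians, ..., all mins
    vals[pos + 1:21] <- as.vector(ax)        # column-major: stat by stat, axes x,y,z
    vals[pos + 22L] <- slope(sx, sy, sz)
    pos <- pos + 22L
  }
  out <- tibble::as_tibble(as.list(stats::setNames(vals, feature_names(scheme))))
  out
}

#' Extract features for a dataset of single-event traces
#'
#' Maps [window_features()] over a tibble of labeled event traces (as
#' produced by [gen_event_dataset()]), returning the standard feature
#' table: one row per event, `22 * m` named feature columns, then `label`
#' and `subject_id`.
#'
#' @param events a tibble with list-column `trace` and columns `label`,
#'   `subject_id`.
#' @param scheme a [window_scheme()].
#' @return a tibble of `nrow(events)` rows.
#' @export
extract_features <- function(events, scheme = window_scheme()) {
  stopifnot(is.data.frame(events), "trace" %in% names(events))
  feats <- purrr::map(events$trace, function(tr) {
    seg <- segment_event(tr, scheme)
    window_features(tr, scheme, seg$start_sample)
  })
  out <- dplyr::bind_rows(feats)
  out$label <- events$label
  out$subject_id <- events$subject_id
  out
}

#' Read / write a feature table
#'
#' Feature tables are plain CSV: one row per event, named feature columns,
#' trailing `label` and `subject_id` columns.
#'
#' @param features a feature tibble (as from [extract_features()]).
#' @param path CSV path.
#' @return `read_features()` returns the tibble; `write_features()` the
#'   path, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Control feature sets
#'
#' Baseline variants of the default two-sub-window feature table used as
#' experimental controls: `"2s1"` keeps only the 22 features of the first
#' (pre-impact) sub-window, `"2s2"` only those of the second (impact)
#' sub-window, and `"3s"` recomputes 22 features over the undivided 3 s
#' window. `"3s2sub"` returns the input unchanged.
#'
#' @param events a single-event dataset tibble (needed for `"3s"`, which
#'   re-extracts), or `NULL` when `control` is a column subset.
#' @param features a default-scheme feature table from
#'   [extract_features()].
#' @param control one of `"3s2sub"`, `"2s1"`, `"2s2"`, `"3s"`.
#' @return a feature tibble with 44 (`3s2sub`) or 22 feature columns plus
#'   `label` and `subject_id`.
#' @export
control_feature_set <- function(features, control = c("3s2sub", "2s1", "2s2", "3s"),
                                events = NULL) {
  control <- match.arg(control)
  if (control == "3s2sub") return(features)
  if (control == "3s") {
    if (is.null(events)) abort_usage("the '3s' control needs the event traces to re-extract")
    return(extract_features(events, window_scheme(3, 1, 0)))
  }
  suffix <- if (control == "2s1") "1" else "2"
  keep <- feature_cols(features)
  keep <- keep[endsWith(keep, suffix)]
  features[c(keep, intersect(c("label", "subject_id"), names(features)))]
}

#' Names of the feature columns of a feature table
#' @param features a feature tibble.
#' @return character vector of feature column names (everything numeric
#'   except bookkeeping columns).
#' @keywords internal
feature_cols <- function(features) {
  setdiff(names(features), c("label", "subject_id", "subtype", "event_id", "window",
                             "start_sample", "length_samples", "start_s", "end_s"))
}
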