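#' Window / sub-window segmentation scheme
#'
#' A motion window of `n_s` seconds split into `m` sub-windows with
#' pairwise overlap fraction `o`. The sub-window length in seconds is
#' `L = n_s / (m - (m - 1) * o)`; for `m = 1` the sub-window is the whole
#' window regardless of `o`. The default scheme (3 s, 2 sub-windows, 50%
#' overlap) gives two 2 s sub-windows sharing 1 s, matching the two-phase
#' structure of a fall: pre-impact motion in the first sub-window, impact
#' and rest in the second.
#'
#' @param n_s window length in seconds (> 0).
#' @param m sub-window count (integer >= 1).
#' @param o overlap fraction between consecutive sub-windows, in `[0, 1)`.
#' @return a `window_scheme` object.
#' @examples
#' window_scheme()            # the 3s2sub default
#' window_scheme(3, 1, 0)     # whole-window control ("3s")
#' @export
window_scheme <- function(n_s = 3, m = 2, o = 0.5) {
  if (!is.numeric(n_s) || n_s <= 0) abort_usage("n_s must be > 0")
  if (!is.numeric(m) || m < 1 || m != round(m)) abort_usage("m must be an integer >= 1")
  if (!is.numeric(o) || o < 0 || o >= 1) abort_usage("o must lie in [0, 1)")
  m <- as.integer(m)
  L_s <- if (m == 1L) n_s else n_s / (m - (m - 1) * o)
  structure(list(n_s = n_s, m = m, o = o, subwindow_s = L_s),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> %gs window, %d sub-window(s), overlap %g (sub-window %.3g s)\n",
              x$n_s, x$m, x$o, x$subwindow_s))
  invisible(x)
}

#' Sub-window sample bounds for a scheme at a given rate
#'
#' Returns the `m` half-open sample intervals `[start, end)` (0-based) of
#' the sub-windows inside one window. Lengths are rounded to whole samples
#' (`L_samp = round(L_s * rate)`, hop `= round((1 - o) * L_samp)`) and the
#' last sub-window is anchored to end exactly at `round(n_s * rate)` so
#' rounding error cannot accumulate.
#'
#' @param scheme a [window_scheme()].
#' @param rate sampling rate in Hz.
#' @return a tibble with columns `sub`, `start`, `end` (0-based half-open).
#' @examples
#' subwindow_bounds(window_scheme(3, 2, 0.5), 50)  # (0,100) and (50,150)
#' @export
subwindow_bounds <- function(scheme, rate) {
  stopifnot(inherits(scheme, "window_scheme"))
  n_samp <- as.integer(round(scheme$n_s * rate))
  L <- as.integer(round(scheme$subwindow_s * rate))
  if (L < 1L) abort_usage("sub-window rounds to 0 samples at this rate")
  if (scheme$m == 1L) {
    return(tibble::tibble(sub = 1L, start = 0L, end = n_samp))
  }
  hop <- as.integer(round((1 - scheme$o) * L))
  if (hop < 1L) abort_usage("sub-window hop rounds to 0 samples at this rate")
  starts <- (seq_len(scheme$m) - 1L) * hop
  starts[scheme$m] <- n_samp - L   # anchor the last sub-window at the window end
  if (starts[scheme$m] < 0L) abort_usage("sub-windows do not fit in the window")
  if (scheme$m > 1L && any(diff(starts) > L)) {
    abort_usage("sub-windows leave a gap inside the window at this rate")
  }
  tibble::tibble(sub = seq_len(scheme$m), start = as.integer(starts),
                 end = as.integer(starts + L))
}

#' Segment a single-event trace into its one analysis window
#'
#' Single-event recordings carry exactly one activity; the analysis window
#' is anchored at sample 0 with length `round(n_s * rate)`. A trace longer
#' by at most one sample is truncated (some corpora store 151 samples for a
#' nominal 3 s at 50 Hz); anything longer or shorter is an error.
#'
#' @param trace a [triaxial_trace()].
#' @param scheme a [window_scheme()].
#' @return a one-row tibble with columns `start_sample`, `length_samples`
#'   (0-based sample indexing).
#' @export
segment_event <- function(trace, scheme = window_scheme()) {
  n_samp <- as.integer(round(scheme$n_s * trace_rate(trace)))
  n <- nrow(trace)
  if (n < n_samp) {
    abort_usage(sprintf("trace too short: %d samples, window needs %d", n, n_samp))
  }
  if (n > n_samp + 1L) {
    abort_usage(sprintf("trace has %d samples; at most %d (window + 1) accepted", n, n_samp + 1L))
  }
  tibble::tibble(start_sample = 0L, length_samples = n_samp)
}

#' Streaming window configuration
#'
#' Sliding-window parameters for continuous recordings: window length `W`
#' seconds and overlap fraction `o`, giving hop `H = W * (1 - o)`. The
#' decision for window index `t` (0-based) is available only at time
#' `t * H + W` — the window's end — so no decision looks ahead of the data
#' it has seen.
#'
#' @param window_s window length W in seconds.
#' @param overlap overlap fraction in `[0, 1)`.
#' @return a `stream_config` object.
#' @export
stream_config <- function(window_s = 3, overlap = 0.5) {
  if (window_s <= 0) abort_usage("window_s must be > 0")
  if (overlap < 0 || overlap >= 1) abort_usage("overlap must lie in [0, 1)")
  structure(list(window_s = window_s, overlap = overlap,
                 hop_s = window_s * (1 - overlap)),
            class = "stream_config")
}

#' Enumerate sliding windows over a continuous trace
#'
#' Windows of `round(W * rate)` samples every `round(H * rate)` samples,
#' all fully inside the trace (a trailing partial window is dropped, never
#' padded). With `N` samples the count is
#' `floor((N - W_samp) / H_samp) + 1`.
#'
#' @param trace a [triaxial_trace()].
#' @param cfg a [stream_config()].
#' @return a tibble with columns `window` (1-based index), `start_sample`
#'   (0-based), `length_samples`, `start_s`, `end_s` (the decision time).
#'   Empty (zero rows) if the trace is shorter than one window.
#' @export
slide_windows <- function(trace, cfg = stream_config()) {
  stopifnot(inherits(cfg, "stream_config"))
  rate <- trace_rate(trace)
  W <- as.integer(round(cfg$window_s * rate))
  H <- as.integer(round(cfg$hop_s * rate))
  if (H < 1L) abort_usage("hop rounds to 0 samples at this rate")
  N <- nrow(trace)
  if (N < W) {
    return(tibble::tibble(window = integer(), start_sample = integer(),
                          length_samples = integer(), start_s = numeric(),
                          end_s = numeric()))
  }
  k <- (N - W) %/% H
  starts <- (0:k) * H
  tibble::tibble(
    window = seq_len(k + 1L),
    start_sample = as.integer(starts),
    length_samples = W,
    start_s = starts / rate,
    end_s = (starts + W) / rate
  )
}
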