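#' Tri-axial accelerometer trace
#'
#' A `triaxial_trace` is a tibble with columns `x`, `y`, `z` (acceleration in
#' g on the three sensor axes, sample `i` taken at time `(i - 1) / rate`
#' seconds) carrying the recording metadata as attributes: sampling `rate`
#' (Hz), symmetric sensor `range_g`, an opaque `subject_id`, the sensor
#' `position`, and a tibble of fall `annotations` (`start_s`, `end_s`,
#' `label`, in seconds from the first sample).
#'
#' @param x,y,z numeric vectors of equal length (acceleration in g).
#' @param rate sampling rate in Hz, > 0.
#' @param range_g symmetric sensor range in g (smartphone accelerometers are
#'   typically clipped at 2 g; some body-worn sensors at 6 g).
#' @param subject_id identifier of the wearer, or `NA`.
#' @param position one of `"pocket"`, `"lower_back"`, `"thigh"`, `"unknown"`.
#' @param annotations `NULL`, or a data frame with columns `start_s`,
#'   `end_s`, `label` marking true fall intervals.
#' @return a `triaxial_trace` object (a tibble subclass).
#' @examples
#' tr <- triaxial_trace(x = rnorm(150, 0, 0.02), y = rnorm(150, 0, 0.02),
#'                      z = rnorm(150, 1, 0.02), rate = 50)
#' trace_duration(tr)
#' @export
triaxial_trace <- function(x, y, z, rate, range_g = 2,
                           subject_id = NA_character_,
                           position = c("unknown", "pocket", "lower_back", "thigh"),
                           annotations = NULL) {
  position <- match.arg(position)
  assert_finite_numeric(x, "axis x")
  assert_finite_numeric(y, "axis y")
  assert_finite_numeric(z, "axis z")
  n <- length(x)
  if (n < 1L || length(y) != n || length(z) != n) {
    abort_usage("all three axes must have identical length >= 1")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort_usage("rate must be a single positive number (Hz)")
  }
  if (!is.numeric(range_g) || range_g <= 0) {
    abort_usage("range_g must be positive")
  }
  if (max(abs(c(x, y, z))) > range_g + 1e-9) {
    abort_data(sprintf("samples exceed the stated sensor range of +/-%g g", range_g))
  }
  ann <- validate_annotations(annotations, n / rate)
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  structure(out,
    rate = rate, range_g = range_g,
    subject_id = as.character(subject_id), position = position,
    annotations = ann,
    class = c("triaxial_trace", class(out))
  )
}

validate_annotations <- function(annotations, duration_s) {
  if (is.null(annotations) || NROW(annotations) == 0L) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(), label = character()))
  }
  ann <- tibble::as_tibble(annotations)
  if (!all(c("start_s", "end_s") %in% names(ann))) {
    abort_usage("annotations need columns start_s and end_s")
  }
  if (!"label" %in% names(ann)) ann$label <- "fall"
  ann <- ann[c("start_s", "end_s", "label")]
  bad <- ann$start_s < 0 | ann$start_s >= ann$end_s | ann$end_s > duration_s + 1e-9
  if (any(bad)) {
    abort_usage(sprintf(
      "annotation %d outside [0, %.3f] or with start >= end", which(bad)[1], duration_s))
  }
  ann
}

#' @export
print.triaxial_trace <- function(x, ...) {
  cat(sprintf(
    "<triaxial_trace> %d samples @ %g Hz (%.2f s), range +/-%g g, subject %s, %d annotation(s)\n",
    nrow(x), trace_rate(x), trace_duration(x), attr(x, "range_g"),
    attr(x, "subject_id"), nrow(trace_annotations(x))))
  NextMethod()
}

#' Trace accessors
#'
#' @param trace a [triaxial_trace()].
#' @return `trace_rate()` the sampling rate in Hz; `trace_duration()` the
#'   duration `n / rate` in seconds; `trace_annotations()` the annotation
#'   tibble; `trace_subject()` the subject identifier.
#' @export
trace_rate <- function(trace) attr(trace, "rate")

#' @rdname trace_rate
#' @export
trace_duration <- function(trace) nrow(trace) / trace_rate(trace)

#' @rdname trace_rate
#' @export
trace_annotations <- function(trace) attr(trace, "annotations")

#' @rdname trace_rate
#' @export
trace_subject <- function(trace) attr(trace, "subject_id")

#' Read a tri-axial trace from CSV
#'
#' Two dialects are supported: `time_xyz` (columns `t,x,y,z`, `t` in
#' seconds on a uniform grid, from which the rate is inferred) and `xyz`
#' (columns `x,y,z`, requiring `rate_hint`). An optional JSON sidecar
#' `<name>.meta.json` next to the file supplies rate, range, subject,
#' position and annotations; values in the sidecar win over `rate_hint`.
#'
#' @param path CSV file path.
#' @param rate_hint sampling rate in Hz; required for the `xyz` dialect
#'   when no sidecar is present.
#' @param dialect `"auto"` (from the header), `"time_xyz"` or `"xyz"`.
#' @return a [triaxial_trace()].
#' @export
read_trace <- function(path, rate_hint = NULL, dialect = c("auto", "time_xyz", "xyz")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  # readr warns on parse problems; we inspect problems() and error ourselves
  dat <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE))
  probs <- readr::problems(dat)
  if (nrow(probs) > 0L) {
    # problems()$row counts file lines including the header
    abort_data(sprintf("parse error in %s at line %d: expected %s, got '%s'",
                       path, probs$row[1], probs$expected[1], probs$actual[1]))
  }
  meta <- read_sidecar(path)
  if (dialect == "auto") {
    dialect <- if ("t" %in% names(dat)) "time_xyz" else "xyz"
  }
  if (!all(c("x", "y", "z") %in% names(dat))) {
    abort_data(sprintf("%s: expected columns x,y,z (found: %s)",
                       path, paste(names(dat), collapse = ",")))
  }
  if (dialect == "time_xyz") {
    if (!"t" %in% names(dat)) abort_data("time_xyz dialect needs a 't' column")
    tt <- dat$t
    if (nrow(dat) < 2L) abort_data("need >= 2 samples to infer a rate from time")
    dt <- diff(tt)
    if (any(dt <= 0)) abort_data("time column must be strictly increasing")
    if (max(abs(dt - dt[1])) > 1e-6 * max(dt[1], 1e-12)) {
      abort_data("time column is not a uniform grid (relative tolerance 1e-6)")
    }
    rate <- 1 / dt[1]
  } else {
    rate <- meta$rate %||% rate_hint
    if (is.null(rate)) abort_usage("xyz dialect requires rate_hint (or a sidecar with rate)")
  }
  rate <- meta$rate %||% rate
  triaxial_trace(
    dat$x, dat$y, dat$z, rate = rate,
    range_g = meta$range_g %||% max(2, ceiling(max(abs(c(dat$x, dat$y, dat$z))))),
    subject_id = meta$subject_id %||% NA_character_,
    position = meta$position %||% "unknown",
    annotations = meta$annotations
  )
}

sidecar_path <- function(path) sub("\\.csv$", "", path) |> paste0(".meta.json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(meta$annotations) && NROW(meta$annotations) > 0) {
    meta$annotations <- tibble::as_tibble(meta$annotations)
  } else {
    meta$annotations <- NULL
  }
  meta
}

#' Write a tri-axial trace to CSV (plus JSON metadata sidecar)
#'
#' Samples go to `<path>` in the `xyz` dialect; rate, range, subject,
#' position and annotations go to `<name>.meta.json` so that
#' `read_trace()` round-trips the trace (samples to 1e-9, rate exactly).
#'
#' @param trace a [triaxial_trace()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "triaxial_trace"))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_usage(sprintf("directory does not exist: %s", dir))
  dat <- tibble::tibble(x = trace$x, y = trace$y, z = trace$z)
  tryCatch(readr::write_csv(dat, path, progress = FALSE),
           error = function(e) abort_usage(sprintf("cannot write %s: %s", path, conditionMessage(e))))
  meta <- list(
    rate = trace_rate(trace), range_g = attr(trace, "range_g"),
    subject_id = attr(trace, "subject_id"), position = attr(trace, "position"),
    annotations = trace_annotations(trace)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resample a trace to a new rate
#'
#' `decimate` keeps every (source/target)-th sample starting at index 0 and
#' requires an integer ratio (no anti-alias filter; plain sample dropping).
#' `linear` evaluates per-axis piecewise-linear interpolants on the uniform
#' target grid starting at t = 0, covering the source time span
#' `(n - 1) / rate`. Annotations are in seconds and carry over unchanged.
#'
#' @param trace a [triaxial_trace()].
#' @param target_rate new rate in Hz.
#' @param method `"linear"` (default; exact on affine signals) or
#'   `"decimate"`.
#' @return a [triaxial_trace()] at `target_rate`.
#' @export
resample_trace <- function(trace, target_rate, method = c("linear", "decimate")) {
  method <- match.arg(method)
  rate <- trace_rate(trace)
  if (target_rate <= 0) abort_usage("target_rate must be positive")
  if (method == "decimate") {
    ratio <- rate / target_rate
    if (abs(ratio - round(ratio)) > 1e-9) {
      abort_usage(sprintf(
        "decimation needs source rate (%g) to be an integer multiple of target (%g); use method = 'linear'",
        rate, target_rate))
    }
    idx <- seq(1L, nrow(trace), by = as.integer(round(ratio)))
    new <- list(x = trace$x[idx], y = trace$y[idx], z = trace$z[idx])
  } else {
    span <- (nrow(trace) - 1L) / rate
    tt_new <- seq(0, span, by = 1 / target_rate)
    tt_old <- (seq_len(nrow(trace)) - 1L) / rate
    new <- lapply(trace[c("x", "y", "z")], function(v) {
      stats::approx(tt_old, v, xout = tt_new, method = "linear")$y
    })
  }
  triaxial_trace(new$x, new$y, new$z, rate = target_rate,
                 range_g = attr(trace, "range_g"),
                 subject_id = attr(trace, "subject_id"),
                 position = attr(trace, "position"),
                 annotations = trace_annotations(trace))
}

#' Clamp a trace to a symmetric sensor range
#'
#' Emulates accelerometer saturation: every sample is clamped to
#' `[-limit_g, limit_g]` and the trace's `range_g` is set to `limit_g`.
#' Idempotent.
#'
#' @param trace a [triaxial_trace()].
#' @param limit_g positive clipping limit in g.
#' @return a clipped [triaxial_trace()].
#' @export
clip_range <- function(trace, limit_g) {
  if (!is.numeric(limit_g) || limit_g <= 0) abort_usage("limit_g must be positive")
  clamp <- function(v) pmin(pmax(v, -limit_g), limit_g)
  triaxial_trace(clamp(trace$x), clamp(trace$y), clamp(trace$z),
                 rate = trace_rate(trace), range_g = limit_g,
                 subject_id = attr(trace, "subject_id"),
                 position = attr(trace, "position"),
                 annotations = trace_annotations(trace))
}
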