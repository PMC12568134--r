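#' Plot a tri-axial trace
#'
#' Lines per axis with annotated fall intervals shaded.
#'
#' @param object a [triaxial_trace()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.triaxial_trace <- function(object, ...) {
  rate <- trace_rate(object)
  dat <- tibble::tibble(
    t = (seq_len(nrow(object)) - 1L) / rate,
    x = object$x, y = object$y, z = object$z
  ) |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "axis", values_to = "g")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$g, colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "acceleration [g]") +
    ggplot2::theme_minimal()
  ann <- trace_annotations(object)
  if (nrow(ann) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ann, inherit.aes = FALSE, alpha = 0.15, fill = "red",
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s, ymin = -Inf, ymax = Inf))
  }
  p
}

#' Plot per-fold metrics of a cross-validation result
#'
#' @param object a `cv_result`.
#' @param metrics metric columns to show.
#' @param ... unused.
#' @return a ggplot (boxplot per metric over folds).
#' @export
autoplot.cv_result <- function(object, metrics = c("accuracy", "sensitivity",
                                                   "specificity", "f1", "maa"), ...) {
  dat <- tidyr::pivot_longer(object$folds[metrics], dplyr::everything(),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

#' Plot a streaming result
#'
#' Alarm raster over time with annotated fall intervals.
#'
#' @param object a `streaming_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.streaming_result <- function(object, ...) {
  dec <- object$decisions
  ggplot2::ggplot(dec, ggplot2::aes(x = .data$decision_time_s,
                                    y = as.integer(.data$label == object$positive))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "decision time [s]", y = "alarm") +
    ggplot2::theme_minimal()
}

#' Plot an attribution
#'
#' Signed per-feature contributions, largest magnitudes first (a tabular
#' stand-in for a force display).
#'
#' @param object an `attribution`.
#' @param top_n number of features to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.attribution <- function(object, top_n = 10, ...) {
  dat <- dplyr::slice_max(object$phi, order_by = abs(.data$phi), n = top_n)
  dat$feature <- factor(dat$feature, levels = rev(dat$feature))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phi, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "phi (score units)", y = NULL) +
    ggplot2::theme_minimal()
}
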