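#' Plot an entropy series
#'
#' Per-window entropy against window start time, one line per q.
#'
#' @param object An `entropy_series` from [sliding_entropy()].
#' @param rate Optional sampling rate to put the x axis in seconds
#'   (otherwise samples).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.entropy_series <- function(object, rate = NULL, ...) {
  df <- tibble::as_tibble(object)
  xlab <- "window start (samples)"
  if (!is.null(rate)) {
    df$start <- df$start / rate
    xlab <- "window start (s)"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$start, .data$entropy,
                                   colour = factor(.data$q))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "Tsallis entropy", colour = "q") +
    ggplot2::theme_minimal()
}

#' Plot a result table
#'
#' Mean accuracy per unit, faceted by axis and q, with the mean F-score
#' overlaid as points.
#'
#' @param object A `ts_result` from [run_experiment()].
#' @param axis Which axis to show (default all present).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ts_result <- function(object, axis = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(axis)) df <- df[df$axis == axis, , drop = FALSE]
  df <- df[!df$flagged, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$unit, .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_f_score), size = 0.8) +
    ggplot2::facet_grid(ggplot2::vars(.data$q), ggplot2::vars(.data$axis),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "mean accuracy (bars) / mean F-score (points)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot a scalp topology
#'
#' Draws the head outline (unit circle, nose up) with every electrode at
#' its 2-D position; marked electrodes are highlighted.
#'
#' @param object A `ts_topology` from [export_topology()].
#' @param label_size Text size for electrode labels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ts_topology <- function(object, label_size = 2, ...) {
  theta <- seq(0, 2 * pi, length.out = 200)
  head <- tibble::tibble(x = 1.08 * cos(theta), y = 1.08 * sin(theta))
  nose <- tibble::tibble(x = c(-0.1, 0, 0.1), y = c(1.07, 1.2, 1.07))
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = head, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = nose, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$marked), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       size = label_size, vjust = -1.1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "selected")
}
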