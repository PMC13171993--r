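#' Plot a session timeline
#'
#' One horizontal segment per executed phase, colored by the cause that
#' ended it, so participant-driven triggers, timeouts and overrides are
#' visible at a glance across the session.
#'
#' @param transitions Transition tibble from [run_session()].
#' @return A ggplot object.
#' @export
plot_session_timeline <- function(transitions) {
  d <- transitions |>
    mutate(onset = .data$t_ms - .data$latency_ms,
           trial = factor(.data$trial_id, levels = unique(.data$trial_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$onset / 1000,
                                  xend = .data$t_ms / 1000,
                                  y = .data$trial, yend = .data$trial,
                                  colour = .data$cause)) +
    ggplot2::geom_segment(linewidth = 2.5) +
    ggplot2::labs(x = "session time (s)", y = NULL, colour = "phase ended by") +
    ggplot2::theme_minimal()
}

#' Plot gaze samples over the ROI layout
#'
#' Scanpath-style diagnostic: the ROI rectangles of a trial with the raw
#' gaze samples (valid samples as points, invalid greyed).
#'
#' @param samples Gaze tibble.
#' @param rois ROI tibble.
#' @param n_max Thin the stream to at most this many samples.
#' @return A ggplot object.
#' @export
plot_gaze <- function(samples, rois, n_max = 5000) {
  if (nrow(samples) > n_max)
    samples <- samples[seq(1L, nrow(samples), length.out = n_max), ]
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = rois,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1, ymin = .data$y0,
                   ymax = .data$y1),
      fill = NA, colour = "red"
    ) +
    ggplot2::geom_text(
      data = rois,
      ggplot2::aes(x = (.data$x0 + .data$x1) / 2, y = .data$y0 - 10,
                   label = .data$id),
      colour = "red", size = 3
    ) +
    ggplot2::geom_point(
      data = samples,
      ggplot2::aes(x = .data$x_px, y = .data$y_px, alpha = .data$valid),
      size = 0.4
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.6, `FALSE` = 0.1),
                                guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a session summary
#'
#' Bar chart of per-construct success rates over analysable trials.
#'
#' @param object A `ja_session_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ja_session_summary <- function(object, ...) {
  d <- object$by_construct
  ggplot2::ggplot(d, ggplot2::aes(x = .data$task, y = .data$success_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "success rate (valid trials)") +
    ggplot2::theme_minimal()
}
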