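#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the residual-error time course of an experiment
#'
#' Mean residual tracking error (error minus per-trial baseline) over time
#' across all trials, with a +/- SD ribbon, per decoder and noise profile;
#' the vertical line marks the noise onset.
#'
#' @param object An `offline_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.offline_experiment <- function(object, ...) {
  dat <- object$error_curves
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$mean_residual,
                                    colour = .data$decoder, fill = .data$decoder)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_residual - .data$sd_residual,
                                      ymax = .data$mean_residual + .data$sd_residual),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 5, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.3, linetype = "dotted") +
    ggplot2::facet_wrap(~profile, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "residual error (MVC units)",
                  colour = "decoder", fill = "decoder") +
    ggplot2::theme_minimal()
}

#' @export
plot.offline_experiment <- function(x, ...) print(autoplot(x, ...))

#' Plot a decoded cursor trajectory in the 2-D control space
#'
#' @param cursor A cursor tibble from [decode_stream()].
#' @param target Optional length-2 target centre; drawn with its 0.15-unit
#'   radius.
#' @param radius Target radius (default 0.15).
#' @return A ggplot object.
#' @export
plot_cursor <- function(cursor, target = NULL, radius = 0.15) {
  p <- ggplot2::ggplot(cursor, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$time)) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::annotate("path",
      x = cos(seq(0, 2 * pi, length.out = 181)),
      y = sin(seq(0, 2 * pi, length.out = 181)), linetype = "dotted"
    ) +
    ggplot2::labs(x = "flexion (-) / extension (+)",
                  y = "ulnar (-) / radial (+)", colour = "time (s)") +
    ggplot2::theme_minimal()
  if (!is.null(target)) {
    ang <- seq(0, 2 * pi, length.out = 91)
    p <- p + ggplot2::annotate("path", x = target[1] + radius * cos(ang),
                               y = target[2] + radius * sin(ang), colour = "red")
  }
  p
}

#' Plot a few channels of an EMG recording
#'
#' Channels are stacked with a vertical offset; long recordings are
#' down-sampled for display.
#'
#' @param object An [emg_recording()].
#' @param channels Channels to show (default all).
#' @param max_points Maximum samples per channel to draw (default 20000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_recording <- function(object, channels = seq_len(n_channels(object)),
                                   max_points = 20000, ...) {
  step <- max(1L, n_samples(object) %/% max_points)
  idx <- seq(1L, n_samples(object), by = step)
  offset <- 2.5 * stats::median(apply(object$signals, 2, stats::sd)) + 1e-12
  dat <- purrr::map_dfr(seq_along(channels), function(i) {
    ch <- channels[i]
    tibble::tibble(time = (idx - 1) / object$fs,
                   value = object$signals[idx, ch] + (i - 1) * 4 * offset,
                   channel = colnames(object$signals)[ch])
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value,
                                    group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "signal (offset per channel)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
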