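# ggplot2 views of the core result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spatial firing rate map
#'
#' @param object An `mec_ratemap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mec_ratemap <- function(object, ...) {
  nb <- nrow(object$rates)
  df <- tidyr::expand_grid(ix = seq_len(nb), iy = seq_len(nb))
  df$x <- (df$ix - 0.5) * object$bin_size
  df$y <- (df$iy - 0.5) * object$bin_size
  df$rate <- object$rates[cbind(df$ix, df$iy)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "Hz") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a head-direction tuning curve
#'
#' @param object An `mec_hdtuning`.
#' @param ... Unused.
#' @return A ggplot (polar).
#' @export
autoplot.mec_hdtuning <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$hd * 180 / pi, .data$rate)) +
    ggplot2::geom_col(width = 6, fill = "steelblue") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::labs(x = NULL, y = "rate (Hz)",
                  subtitle = sprintf("MRL %.2f, preferred %.0f°",
                                     object$mrl,
                                     object$preferred * 180 / pi)) +
    ggplot2::theme_minimal()
}

#' Plot a grid-score rotation-correlation curve
#'
#' @param object An `mec_gridscore`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mec_gridscore <- function(object, ...) {
  assert_that(!is.null(object$curve), "grid score undefined; nothing to plot")
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$angle, .data$r)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_vline(xintercept = seq(60, 300, 60), linetype = 3) +
    ggplot2::labs(x = "rotation (deg)", y = "Pearson r",
                  subtitle = sprintf("grid score %.3f", object$score)) +
    ggplot2::theme_minimal()
}

#' Plot theta-frequency speed tuning per condition
#'
#' @param signals Output of [derive_signals()].
#' @param epochs Epoch table.
#' @param speed_range Plotted speed range, cm/s.
#' @return A ggplot of binned mean theta frequency vs speed by
#'   condition.
#' @export
plot_theta_speed <- function(signals, epochs, speed_range = c(2, 30)) {
  cond <- rep(NA_character_, nrow(signals))
  for (i in seq_len(nrow(epochs))) {
    sel <- signals$t >= epochs$start[i] & signals$t < epochs$end[i]
    cond[sel] <- epochs$condition[i]
  }
  df <- tibble::tibble(speed = signals$speed, f = signals$theta_freq,
                       condition = cond) |>
    dplyr::filter(!is.na(.data$f), !is.na(.data$condition),
                  .data$speed >= speed_range[1],
                  .data$speed <= speed_range[2]) |>
    dplyr::mutate(speed_bin = floor(.data$speed / 2) * 2 + 1) |>
    dplyr::group_by(.data$condition, .data$speed_bin) |>
    dplyr::summarise(f = mean(.data$f), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$speed_bin, .data$f,
                                   color = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(light = "firebrick",
                                           dark = "gray25")) +
    ggplot2::labs(x = "running speed (cm/s)", y = "theta frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a metric time course
#'
#' @param tc A [timecourse()] table.
#' @param metric Metric column.
#' @return A ggplot.
#' @export
plot_timecourse <- function(tc, metric) {
  ggplot2::ggplot(tc, ggplot2::aes(.data$offset, .data[[metric]],
                                   color = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(light = "firebrick",
                                           dark = "gray25")) +
    ggplot2::labs(x = "time in epoch (s)") +
    ggplot2::theme_minimal()
}
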