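#' Plot an activation map
#'
#' Activation time in ms as a filled raster; never-activated pixels are
#' blank.
#'
#' @param object An [activation_map].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.activation_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$times_ms)),
                           col = seq_len(ncol(object$times_ms)))
  df$time_ms <- object$times_ms[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$time_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "activation (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Activation map (beat %d, theta = %g)",
                      object$beat_index, object$theta),
      x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot a space-time diagram
#'
#' @param object A `space_time` matrix from [space_time_plot()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.space_time <- function(object, ...) {
  dt <- attr(object, "frame_interval")
  px <- attr(object, "pixel_size")
  m <- unclass(object)
  df <- tidyr::expand_grid(pos = seq_len(nrow(m)), frame = seq_len(ncol(m)))
  df$intensity <- m[cbind(df$pos, df$frame)]
  ggplot2::ggplot(df, ggplot2::aes((.data$frame - 1) * dt / 1000,
                                   (.data$pos - 1) * px,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "F (norm)") +
    ggplot2::labs(x = "time (s)", y = "position (um)",
                  title = "Space-time plot") +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence trace with detected transients
#'
#' @param object A `transient_metrics` result from [detect_transients()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.transient_metrics <- function(object, ...) {
  tr <- object$trace
  df <- as_tibble(tr)
  pk <- tibble::tibble(time_ms = object$peak_times,
                       value = tr$samples[object$peak_frames])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000, .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = pk, colour = "red", size = 2) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  title = sprintf("%s: %d transient(s)", object$roi_id,
                                  length(object$peak_times))) +
    ggplot2::theme_minimal()
}

#' Plot an I-V curve
#'
#' @param iv A tibble from [iv_curve()].
#' @return A ggplot object.
#' @export
plot_iv_curve <- function(iv) {
  ggplot2::ggplot(iv, ggplot2::aes(.data$voltage_mV,
                                   .data$current_density)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "step potential (mV)",
                  y = "current density (pA/pF)", title = "I-V curve") +
    ggplot2::theme_minimal()
}

#' Scatter plot of CaT50 against spontaneous interval
#'
#' Reproduces the population layout used to separate regular from
#' irregular cells.
#'
#' @param metrics A tibble from [transient_table()].
#' @return A ggplot object.
#' @export
plot_cat50_scatter <- function(metrics) {
  df <- metrics[!is.na(metrics$cat50_ms) & !is.na(metrics$median_interval_ms), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$median_interval_ms,
                                   .data$cat50_ms, colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spontaneous interval (ms)", y = "CaT50 (ms)") +
    ggplot2::theme_minimal()
}
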