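#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the package's result objects, plus `plot_track()`
#' for a gate trajectory against ground truth and `plot_stratified()` for
#' condition box summaries. All return ggplot objects.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name fetodoppler-plots
NULL

#' @rdname fetodoppler-plots
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "red") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "blue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (a - b)",
                  title = object$label %||% "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' @rdname fetodoppler-plots
#' @method autoplot doppler_spectrogram
#' @export
autoplot.doppler_spectrogram <- function(object, ...) {
  df <- expand.grid(velocity_cms = object$velocity_axis, time_s = object$time)
  df$power <- as.vector(object$power)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$velocity_cms,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "Time (s)", y = "Velocity (cm/s)", fill = "Power") +
    ggplot2::theme_minimal()
}

#' @rdname fetodoppler-plots
#' @method autoplot doppler_envelope
#' @export
autoplot.doppler_envelope <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_s, .data$velocity_cms)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Time (s)", y = "Envelope velocity (cm/s)") +
    ggplot2::theme_minimal()
}

#' @rdname fetodoppler-plots
#' @method autoplot ua_waveform
#' @export
autoplot.ua_waveform <- function(object, ...) {
  ggplot2::ggplot(object$signal,
                  ggplot2::aes(.data$time_s, .data$velocity_cms)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Velocity (cm/s)") +
    ggplot2::theme_minimal()
}

#' @rdname fetodoppler-plots
#' @param trajectory Tibble from [track_sequence()].
#' @param truth Ground-truth tibble (e.g. `frames$truth`).
#' @export
plot_track <- function(trajectory, truth) {
  long <- dplyr::bind_rows(
    dplyr::mutate(trajectory[, c("time_s", "lateral_mm", "axial_mm")],
                  source = "tracked"),
    dplyr::mutate(truth[, c("time_s", "lateral_mm", "axial_mm")],
                  source = "truth"))
  long <- tidyr::pivot_longer(long, c("lateral_mm", "axial_mm"),
                              names_to = "axis", values_to = "mm")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$mm,
                                     colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Position (mm)") +
    ggplot2::theme_minimal()
}

#' @rdname fetodoppler-plots
#' @param strata Output of [stratify()].
#' @export
plot_stratified <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(x = .data$condition)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q25,
                                        ymax = .data$q75),
                           fill = "grey85", width = 0.5) +
    ggplot2::labs(x = NULL, y = attr(strata, "metric") %||% "value") +
    ggplot2::theme_minimal()
}
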