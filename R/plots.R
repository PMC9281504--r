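# ggplot2 views of the main result types.

#' Plot the channels of a wheel time series
#'
#' Faceted line plot of the six force/moment channels plus the total
#' force over time.
#'
#' @param object A [wheel_ts()].
#' @param channels Channels to show (default: forces, mz and total force).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pushrim_ts
#' @export
autoplot.pushrim_ts <- function(object, channels = c("fx", "fy", "fz", "mz"), ...) {
  df <- as_tibble(object) |>
    mutate(ftot = total_force(object)) |>
    tidyr::pivot_longer(all_of(c(channels, "ftot")), names_to = "channel",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = sprintf("%s wheel @ %g Hz", wheel_side(object),
                                  wheel_fs(object)))
}

#' Plot detected pushes over the total force trace
#'
#' Total force with the detection threshold and shaded push intervals;
#' analyzed pushes are darker than transitional ones.
#'
#' @param ts A (preprocessed) [wheel_ts()].
#' @param pushes A `pushrim_pushes` tibble.
#' @param threshold Threshold line to draw (N).
#' @return A ggplot object.
#' @export
plot_pushes <- function(ts, pushes, threshold = 30) {
  df <- tibble(time = ts$time, ftot = total_force(ts))
  shade <- as_tibble(pushes) |>
    mutate(t0 = ts$time[.data$start_index], t1 = ts$time[.data$end_index],
           status = ifelse(.data$analyzed, "analyzed", "transitional"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$ftot)) +
    ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t0, xmax = .data$t1, ymin = -Inf, ymax = Inf,
                   fill = .data$status), alpha = 0.25
    ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(analyzed = "steelblue",
                                          transitional = "grey60")) +
    ggplot2::labs(x = "time [s]", y = "total force [N]", fill = NULL)
}

#' Dot plot of the effect sizes in a study report
#'
#' @param object A `pushrim_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pushrim_report
#' @export
autoplot.pushrim_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect_size, y = .data$parameter,
                                   colour = .data$contrast)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~effect_size_kind, scales = "free_x") +
    ggplot2::labs(x = "effect size", y = NULL, colour = "contrast")
}
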