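#' Plot a recording's channels over time
#'
#' Faceted time-series view of the four physiological channels, with
#' optional concentration-peak markers.
#'
#' @param rec A `conc_recording`.
#' @param events Optional label tibble; peak times are drawn as vertical
#'   lines.
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, events = NULL) {
  long <- tidyr::pivot_longer(tibble::as_tibble(rec), -"time_s",
                              names_to = "column", values_to = "value")
  reg <- channel_info()
  long <- dplyr::mutate(
    long, channel = factor(reg$channel[match(.data$column, reg$column)],
                           levels = reg$channel))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#355e8d") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = sprintf("%s / %s", rec_subject(rec),
                                  attr(rec, "session_id"))) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = events$time_s,
                                 linetype = "dotted", colour = "#d95f02")
  }
  p
}

#' Plot a fusion-sweep result
#'
#' Average AUC per channel subset, ordered as in the sweep (by subset size
#' then canonical channel order).
#'
#' @param sweep Long tibble from [fusion_sweep()].
#' @return A ggplot object.
#' @export
plot_fusion_sweep <- function(sweep) {
  avg <- dplyr::summarise(
    dplyr::group_by(sweep, .data$subset_id, .data$label, .data$size),
    auc = mean(.data$auc), .groups = "drop")
  avg <- dplyr::mutate(avg,
                       label = factor(.data$label,
                                      levels = avg$label[order(avg$subset_id)]))
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$label, y = .data$auc,
                                    fill = factor(.data$size))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Channel subset", y = "Average AUC",
                  fill = "Subset size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
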