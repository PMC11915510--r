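# ggplot2 views of the main result types.

#' Plot a ratio time series by group
#'
#' Per-frame group means with a standard-error ribbon.
#'
#' @param series Ratio tibble (see [ratio_timeseries()]).
#' @return A ggplot object.
#' @export
plot_ratio_timeseries <- function(series) {
  summ <- series |>
    dplyr::filter(is.finite(.data$ratio)) |>
    dplyr::group_by(.data$group, .data$frame) |>
    dplyr::summarise(mean = mean(.data$ratio),
                     sem = sd(.data$ratio) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$frame, y = .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "nucleolus / nucleoplasm ratio") +
    ggplot2::theme_minimal()
}

#' @rdname rm_anova_onset
#' @param object An `onset_anova` object.
#' @method autoplot onset_anova
#' @export
autoplot.onset_anova <- function(object, ...) {
  p <- plot_ratio_timeseries(object$series)
  if (!is.na(object$first_significant)) {
    p <- p + ggplot2::geom_vline(xintercept = object$first_significant,
                                 linetype = "dashed") +
      ggplot2::annotate("text", x = object$first_significant, y = Inf,
                        label = "first significant", vjust = 1.5, hjust = -0.05,
                        size = 3)
  }
  p
}

#' Plot per-condition focus counts
#'
#' @param summary The list from [summarize_foci()].
#' @return A ggplot object.
#' @export
plot_foci_summary <- function(summary) {
  pc <- summary$per_condition
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$condition, y = .data$mean_count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_count - .data$sem_count,
                                        ymax = .data$mean_count + .data$sem_count),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "foci per nucleus") +
    ggplot2::theme_minimal()
}

#' Plot normalised EU measurements by group
#'
#' @param rows EU tibble with a `normalized` column
#'   (see [normalize_to_control()]).
#' @return A ggplot object.
#' @export
plot_eu_by_group <- function(rows) {
  d <- rows[is.finite(rows$normalized), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$normalized)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "EU in FCs (normalised to control)") +
    ggplot2::theme_minimal()
}

#' Plot per-droplet partition ratios
#'
#' @param droplets Per-droplet tibble from [quantify_droplet_field()].
#' @return A ggplot object.
#' @export
plot_droplet_partition <- function(droplets) {
  long <- droplets |>
    dplyr::select(dplyr::any_of(c("droplet_id", "protein_partition",
                                  "probe_partition"))) |>
    tidyr::pivot_longer(-"droplet_id", names_to = "channel",
                        values_to = "partition")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$channel, y = .data$partition)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "partition ratio") +
    ggplot2::theme_minimal()
}
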