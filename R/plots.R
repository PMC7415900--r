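#' Plot longitudinal metric trajectories
#'
#' One panel per metric: thin per-eye traces and the group mean trajectory
#' across weeks.
#'
#' @param long Tidy tibble with `metric`, `animal_id`, `eye`, `week`,
#'   `value` (and optionally `group`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(long) {
  long <- tibble::as_tibble(long)
  if (!"group" %in% names(long)) long$group <- "all"
  means <- long |>
    dplyr::group_by(.data$metric, .data$group, .data$week) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$week, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$animal_id, .data$eye)),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = means, ggplot2::aes(group = .data$group), linewidth = 1) +
    ggplot2::geom_point(data = means) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "week", y = "value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.octa_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(object$height_px),
                           col = seq_len(object$width_px))
  df$value <- as.vector(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "I") +
    ggplot2::theme_void()
}

#' @export
autoplot.octa_rm_anova <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = -log10(.data$p_gg))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(y = "-log10 p (GG-corrected)", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
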