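#' Bar-track plot of dynamic elements and themes
#'
#' The standard one-look summary of a domain: one horizontal track per mode
#' showing its dynamic elements colored by sense (the two opposite-moving
#' parts), with the theme intervals stacked underneath.
#'
#' @param elements Output of [dynamic_elements()].
#' @param themes Optional theme tibble drawn under the DE tracks.
#' @return A ggplot object.
#' @export
plot_de_tracks <- function(elements, themes = NULL) {
  de <- dplyr::mutate(elements,
                      track = paste0("mode ", .data$mode),
                      sense_lab = ifelse(.data$sense > 0, "+", "-"))
  p <- ggplot2::ggplot(de) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$track, yend = .data$track,
                   colour = .data$sense_lab),
      linewidth = 4
    ) +
    ggplot2::scale_colour_manual(values = c("+" = "#b2182b", "-" = "#2166ac"),
                                 name = "sense") +
    ggplot2::labs(x = "residue (local index)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(themes)) {
    th <- dplyr::mutate(themes,
                        track = paste0("theme ", .data$theme_id,
                                       ifelse(.data$variation > 0,
                                              paste0("-", .data$variation), "")))
    p <- p + ggplot2::geom_segment(
      data = th,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$track, yend = .data$track),
      colour = "#1b7837", linewidth = 3
    )
  }
  p
}

#' Eigenvalue spectrum of a mode decomposition
#'
#' @param object A `gnm_modes` object.
#' @param n_modes How many of the slowest modes to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gnm_modes <- function(object, n_modes = 20L, ...) {
  d <- head(tidy(object), n_modes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mode, y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "mode (1 = slowest non-zero)",
                  y = expression(lambda[k])) +
    ggplot2::theme_minimal()
}

#' Per-mode AMI summary plot
#'
#' Mean AMI per mode with the min-max range over all theme combinations,
#' faceted by threshold preset when several are present.
#'
#' @param summaries Output of [mode_theme_summary()] (optionally with
#'   `max_overlap`/`max_gap` columns from [run_domain_analysis()]).
#' @return A ggplot object.
#' @export
plot_mi_summary <- function(summaries) {
  p <- ggplot2::ggplot(summaries, ggplot2::aes(x = factor(.data$mode))) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean_ami,
                                          ymin = .data$min_ami,
                                          ymax = .data$max_ami)) +
    ggplot2::labs(x = "mode", y = "AMI (min / mean / max)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (all(c("max_overlap", "max_gap") %in% names(summaries))) {
    p <- p + ggplot2::facet_wrap(
      ggplot2::vars(paste0("overlap ", .data$max_overlap,
                           ", gap ", .data$max_gap)))
  }
  p
}

#' Null distribution of the maximum MI for one mode
#'
#' @param null_max_mi Numeric vector of per-set maximum MI values.
#' @param real_max_mi The maximum MI of the real theme combinations.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(null_max_mi, real_max_mi) {
  ggplot2::ggplot(tibble(mi = null_max_mi), ggplot2::aes(x = .data$mi)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = real_max_mi, colour = "#b2182b",
                        linewidth = 1) +
    ggplot2::labs(x = "max MI over combinations (nats)", y = "null sets") +
    ggplot2::theme_minimal()
}
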