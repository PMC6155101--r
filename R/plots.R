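# ggplot2 views of descriptors and pattern tables.

#' Plot an angle series along the chain
#'
#' @param object A `barrel_descriptor`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot barrel_descriptor
#' @export
autoplot.barrel_descriptor <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$angle,
                                  colour = .data$type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "window index", y = "dihedral angle (deg)",
                  colour = "type") +
    ggplot2::theme_minimal()
}

#' Histogram plot of dihedral angles
#'
#' @param histogram A tibble from [angle_histogram()], or the `histograms`
#'   element of a [pattern_summary()] (facetted by `type` when present).
#' @return A ggplot.
#' @export
plot_angle_histogram <- function(histogram) {
  p <- ggplot2::ggplot(histogram,
                       ggplot2::aes(x = .data$bin_start + diff(c(
                         histogram$bin_start[1], histogram$bin_end[1])) / 2,
                         y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::labs(x = "dihedral angle (deg)", y = "count") +
    ggplot2::theme_minimal()
  if ("type" %in% names(histogram)) {
    p <- p + ggplot2::facet_wrap(~type)
  }
  p
}

#' Bar chart of dyad or triad pattern counts
#'
#' @param patterns A dyad/triad tibble (`dyads`/`triads` element of a
#'   [pattern_summary()], or a `group_*` table of [aggregate_patterns()]).
#' @return A ggplot facetted by type and, when present, group.
#' @export
plot_pattern_counts <- function(patterns) {
  p <- ggplot2::ggplot(patterns,
                       ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::labs(x = "sign pattern", y = "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  facets <- intersect(c("group", "type"), names(patterns))
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_grid(
      rows = if ("type" %in% facets) ggplot2::vars(.data$type) else NULL,
      cols = if ("group" %in% facets) ggplot2::vars(.data$group) else NULL
    )
  }
  p
}

#' Dyad bar charts for a pattern summary
#'
#' @param object A `pattern_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pattern_summary
#' @export
autoplot.pattern_summary <- function(object, ...) {
  plot_pattern_counts(object$dyads)
}

#' Scatter of angles by position index
#'
#' The per-position view of grouped descriptors: each structure's i-th
#' beta or gamma angle against i.
#'
#' @param positions The `positions` tibble of [aggregate_patterns()].
#' @return A ggplot facetted by type (columns) and group (rows).
#' @export
plot_angle_positions <- function(positions) {
  ggplot2::ggplot(positions,
                  ggplot2::aes(x = .data$type_index, y = .data$angle,
                               colour = factor(.data$n_strands))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group),
                        cols = ggplot2::vars(.data$type)) +
    ggplot2::scale_y_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "position index i", y = "angle (deg)",
                  colour = "n strands") +
    ggplot2::theme_minimal()
}
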