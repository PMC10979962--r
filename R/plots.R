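# ggplot2 renderings of the main result types.

#' Heatmap of a sub-region coherence matrix
#'
#' @param x A `coherence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coherence_matrix <- function(x, ...) {
  m <- unclass(x)
  present <- rownames(m)[!apply(is.na(m), 1, all)]
  df <- expand.grid(layer_a = present, layer_b = present,
                    stringsAsFactors = FALSE)
  df$coherence <- m[cbind(df$layer_a, df$layer_b)]
  df$layer_a <- factor(df$layer_a, levels = present)
  df$layer_b <- factor(df$layer_b, levels = rev(present))
  ggplot2::ggplot(df, ggplot2::aes(.data$layer_a, .data$layer_b,
                                   fill = .data$coherence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(title = sprintf("Theta coherence: %s (%s)",
                                  attr(x, "animal_id"), attr(x, "group")),
                  x = NULL, y = NULL, fill = "coherence") +
    ggplot2::theme_minimal()
}

#' Signed p-value matrix plot for a group comparison
#'
#' Blue cells mark significant coherence decreases, red cells increases.
#'
#' @param comparison A `group_comparison` tibble from [group_pvalue_matrix()].
#' @return A ggplot object.
#' @export
plot_pmatrix <- function(comparison) {
  df <- dplyr::mutate(comparison,
                      layer_a = factor(.data$layer_a, levels = LAYER_ORDER),
                      layer_b = factor(.data$layer_b, levels = rev(LAYER_ORDER)))
  ggplot2::ggplot(df, ggplot2::aes(.data$layer_a, .data$layer_b,
                                   fill = .data$sign)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(decrease = "#2166AC", increase = "#B2182B",
                                          n.s. = "grey95")) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("alpha = %g", attr(comparison, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Polar plot of unit phase preferences
#'
#' Each point is one significantly locked unit at (preferred phase, r);
#' phase 0/360 degrees is the theta peak, 180 degrees the trough.
#'
#' @param locking Phase-locking tibble with `mu`, `r`, `significant` and
#'   optionally `group` columns.
#' @return A ggplot object.
#' @export
plot_phase_locking <- function(locking) {
  df <- dplyr::filter(locking, .data$significant & !is.na(.data$mu))
  df$mu_deg <- rad2deg(df$mu)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mu_deg, .data$r)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270)) +
    ggplot2::labs(x = "preferred theta phase (deg)", y = "r") +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) p <- p + ggplot2::facet_wrap(~group)
  p
}
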