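#' Plot a Ks distribution with WGD-era bin edges
#'
#' Histogram of Ks values, optionally split by category (e.g. intra- vs
#' inter-group), with vertical lines at the bin edges used by
#' [ks_binning()].
#'
#' @param data Tibble with a `ks` column and optionally `category`.
#' @param edges Bin-edge positions (default `c(1.2, 2)`).
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(data, edges = c(1.2, 2),
                                 binwidth = 0.1) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = edges, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Ks (synonymous substitutions per site)",
                  y = "gene pairs") +
    ggplot2::theme_minimal()
  if ("category" %in% colnames(data)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$category),
                                 ncol = 1, scales = "free_y")
  }
  p
}

#' Plot a group-by-group synteny census
#'
#' Tile heatmap of the symmetric group-by-group synteny count matrix from
#' [synteny_census()].
#'
#' @param census A `synteny_census` object.
#' @return A ggplot object.
#' @export
plot_synteny_census <- function(census) {
  stopifnot(inherits(census, "synteny_census"))
  long <- tidyr::pivot_longer(census$matrix, -"group",
                              names_to = "partner", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$partner,
                                     fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot per-group inter-group synteny shares
#'
#' Percentage stacked bar chart of each group's inter-group synteny
#' partners (each bar sums to 100%).
#'
#' @param census A `synteny_census` object.
#' @return A ggplot object.
#' @export
plot_inter_group_shares <- function(census) {
  stopifnot(inherits(census, "synteny_census"))
  ggplot2::ggplot(census$inter_shares,
                  ggplot2::aes(x = .data$group, y = .data$share,
                               fill = .data$partner)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "inter-group synteny share (%)",
                  fill = "partner group") +
    ggplot2::theme_minimal()
}

#' @rdname plot_synteny_census
#' @param object A `synteny_census` object.
#' @param ... Unused.
#' @export
autoplot.synteny_census <- function(object, ...) {
  plot_synteny_census(object)
}
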