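#' Plot a clone map
#'
#' Spot map coloured by inferred clone; point size follows the lattice.
#'
#' @param object A [map_clones()] result.
#' @param graph The [build_spot_graph()] carrying the spot coordinates.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clone_map
#' @export
autoplot.clone_map <- function(object, graph, ...) {
  df <- dplyr::bind_cols(object$assignments,
                         graph$coords[match(object$assignments$spot_id,
                                            graph$nodes), ])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   colour = .data$clone)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "clone",
                  title = "Inferred clone map") +
    ggplot2::theme_minimal()
}

#' Plot a segmentation
#'
#' @param object A segmentation result.
#' @param graph The spot graph with coordinates.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot segmentation_result
#' @export
autoplot.segmentation_result <- function(object, graph, ...) {
  df <- dplyr::bind_cols(object$labels,
                         graph$coords[match(object$labels$spot_id,
                                            graph$nodes), ])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "cluster",
                  title = "Spatial segmentation") +
    ggplot2::theme_minimal()
}

#' Plot clone territories with assigned nuclei
#'
#' Hull outlines per clone, optionally overlaid with nucleus centroids.
#'
#' @param territories A [clone_territories()] object.
#' @param nuclei Optional assigned nucleus tibble.
#' @return A ggplot object.
#' @export
plot_territories <- function(territories, nuclei = NULL) {
  rings <- purrr::imap_dfr(unclass(territories), function(t, cl) {
    purrr::imap_dfr(t$hull$rings, function(r, i) {
      tibble(clone = cl, ring = paste0(cl, "_", i),
             x_um = r[, 1], y_um = r[, 2])
    })
  })
  p <- ggplot2::ggplot(rings,
                       ggplot2::aes(.data$x_um, .data$y_um,
                                    group = .data$ring,
                                    colour = .data$clone)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Clone territories") +
    ggplot2::theme_minimal()
  if (!is.null(nuclei)) {
    p <- p + ggplot2::geom_point(
      data = nuclei,
      ggplot2::aes(.data$x_um, .data$y_um, colour = .data$clone),
      inherit.aes = FALSE, size = 0.3, alpha = 0.4
    )
  }
  p
}

#' Plot heterogeneity indices by group
#'
#' @param indices Tibble with `sample`, `index` and (optionally) `group`.
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(indices) {
  has_group <- "group" %in% names(indices)
  p <- ggplot2::ggplot(
    indices,
    ggplot2::aes(x = if (has_group) .data$group else "all",
                 y = .data$index)
  ) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "clusters (≥ 5 spots) / spots",
                  title = "Spatial heterogeneity index") +
    ggplot2::theme_minimal()
  p
}
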