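#' Map of cluster labels over area centroids
#'
#' @param labels A tibble from [cluster_labels()] (or any data frame with
#'   `area_id` and `cluster`).
#' @param graph The [area_graph()] supplying centroids.
#' @return A ggplot object.
#' @export
plot_cluster_map <- function(labels, graph) {
  d <- left_join(graph$areas, labels, by = "area_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat,
                                  colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "cluster", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sdp_gwr_fit <- function(object, type = c("map", "trace"), ...) {
  type <- match.arg(type)
  if (type == "map") {
    return(plot_cluster_map(cluster_labels(object, "dahl"), object$graph))
  }
  occ <- apply(object$draws$z, 1, function(z) length(unique(z)))
  d <- tibble(draw = seq_along(occ), occupied = occ, b = object$draws$b)
  d <- tidyr::pivot_longer(d, c("occupied", "b"))
  ggplot2::ggplot(d, ggplot2::aes(.data$draw, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "retained draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sdp_sim <- function(object, ...) {
  plot_cluster_map(object$truth, object$graph) +
    ggplot2::labs(colour = "true region")
}

#' @export
autoplot.sdp_replicate_study <- function(object, ...) {
  d <- tidyr::pivot_longer(object$replicates, c("rand_dahl", "rand_mode"),
                           names_prefix = "rand_")
  ggplot2::ggplot(d, ggplot2::aes(.data$name, .data$value)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "Rand index vs truth") +
    ggplot2::theme_minimal()
}
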