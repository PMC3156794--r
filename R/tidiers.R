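#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the networks of a differential analysis
#'
#' Stacks the requested networks of a fitted [run_dc3net()] object into
#' one long edge tibble, distinguishable by the `category` column.
#'
#' @param x A `dc3net` object.
#' @param networks Which networks to include.
#' @param ... Unused.
#' @return A network tibble.
#' @export
tidy.dc3net <- function(x, networks = c(
                          "tnet", "cnet", "test_difnet",
                          "control_difnet", "common", "undecided_test"
                        ), ...) {
  networks <- match.arg(networks, several.ok = TRUE)
  dplyr::bind_rows(x[networks])
}

#' One-row summary of a differential analysis
#'
#' @param x A `dc3net` object.
#' @param ... Unused.
#' @return A one-row tibble with the shared gene count, per-condition MI
#'   thresholds, filter parameters and per-network edge counts.
#' @export
glance.dc3net <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    threshold_test = x$thresholds[["test"]],
    threshold_control = x$thresholds[["control"]],
    rankdif = x$params$rankdif,
    mi_rate = x$params$mi_rate,
    rankdif_common = x$params$rankdif_common,
    mi_rate_common = x$params$mi_rate_common,
    n_tnet = nrow(x$tnet),
    n_cnet = nrow(x$cnet),
    n_test_difnet = nrow(x$test_difnet),
    n_control_difnet = nrow(x$control_difnet),
    n_common = nrow(x$common),
    n_undecided = nrow(x$undecided_test)
  )
}

#' Plot the edge-count decomposition of a differential analysis
#'
#' Bar chart of edge counts per output network: how the test network
#' splits into test-specific, common and undecided interactions, next to
#' the control side.
#'
#' @param object A `dc3net` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dc3net <- function(object, ...) {
  counts <- tidy(object) |>
    dplyr::count(.data$category, name = "edges") |>
    dplyr::mutate(category = factor(.data$category, levels = c(
      "tnet", "test_difnet", "common", "undecided_test", "cnet", "control_difnet"
    )))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$edges)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$edges), vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "edges",
      title = "Differential network decomposition"
    ) +
    ggplot2::theme_minimal()
}

#' Draw a network edge list
#'
#' Lays the network out with a force-directed (Fruchterman-Reingold)
#' layout and draws edges scaled by MI weight. Intended for the small
#' subnetworks produced by [hubs()], [top_edges()] or
#' [filter_by_gene_list()].
#'
#' @param net Network tibble.
#' @param label_nodes Draw gene labels (sensible up to ~100 nodes).
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, label_nodes = TRUE, seed = 1L) {
  if (nrow(net) == 0L) {
    return(ggplot2::ggplot() +
      ggplot2::theme_void() +
      ggplot2::labs(title = "empty network"))
  }
  g <- igraph::graph_from_data_frame(net[, c("gene_a", "gene_b")], directed = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  nodes <- tibble::tibble(
    gene = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L]
  )
  edges <- net |>
    dplyr::left_join(nodes, by = c(gene_a = "gene")) |>
    dplyr::rename(xa = "x", ya = "y") |>
    dplyr::left_join(nodes, by = c(gene_b = "gene")) |>
    dplyr::rename(xb = "x", yb = "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
        linewidth = .data$mi
      ),
      colour = "grey50", alpha = 0.7
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), guide = "none") +
    ggplot2::theme_void()
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = nodes, ggplot2::aes(.data$x, .data$y, label = .data$gene),
      vjust = -0.8, size = 3
    )
  }
  p
}
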