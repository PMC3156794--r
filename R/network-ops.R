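#' Filter a network by a gene list
#'
#' Keeps the edges for which at least one endpoint is in `genes` — the
#' rule used to pull, e.g., oncogene neighbourhoods out of a difnet.
#'
#' @param net Network tibble.
#' @param genes Character vector of gene identifiers (case-sensitive).
#' @return The filtered network tibble.
#' @export
filter_by_gene_list <- function(net, genes) {
  genes <- as.character(genes)
  dplyr::filter(net, .data$gene_a %in% genes | .data$gene_b %in% genes)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Degrees of every gene in a network
#'
#' @param net Network tibble.
#' @return Tibble with columns `gene` and `degree`, descending by degree.
#' @export
node_degrees <- function(net) {
  if (nrow(net) == 0L) return(tibble::tibble(gene = character(), degree = integer()))
  tibble::tibble(gene = c(net$gene_a, net$gene_b)) |>
    dplyr::count(.data$gene, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
}

#' Hub subnetwork
#'
#' Returns the edges incident to at least one hub, a gene whose degree in
#' `net` is strictly greater than `min_degree`. Whole incident edges are
#' kept (not just hub-hub edges) so each hub's neighbourhood stays intact
#' for inspection.
#'
#' @param net Network tibble.
#' @param min_degree Strict degree threshold (>= 0).
#' @return The hub subnetwork tibble.
#' @export
hubs <- function(net, min_degree) {
  stopifnot(min_degree >= 0L)
  deg <- node_degrees(net)
  hub_genes <- deg$gene[deg$degree > min_degree]
  dplyr::filter(net, .data$gene_a %in% hub_genes | .data$gene_b %in% hub_genes)
}

#' Strongest edges of a network
#'
#' The `n` highest-MI edges; ties at the boundary resolved by the
#' lexicographic (gene_a, gene_b) order.
#'
#' @param net Network tibble.
#' @param n Number of edges to keep (>= 0).
#' @return The trimmed network tibble.
#' @export
top_edges <- function(net, n) {
  stopifnot(n >= 0L)
  net |>
    dplyr::arrange(dplyr::desc(.data$mi), .data$gene_a, .data$gene_b) |>
    utils::head(n)
}

#' Connected components of a network
#'
#' Splits the undirected network into its connected components, ordered by
#' descending edge count (ties: descending node count, then the
#' lexicographically smallest member gene). The first element is the
#' highest connected subnetwork.
#'
#' @param net Network tibble.
#' @return A list of network tibbles partitioning the edges of `net`.
#' @export
connected_components <- function(net) {
  if (nrow(net) == 0L) return(list())
  g <- igraph::graph_from_data_frame(net[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  member <- comp$membership[net$gene_a] # both endpoints share a component
  parts <- split(seq_len(nrow(net)), member)
  nets <- lapply(parts, function(idx) net[idx, , drop = FALSE])
  edge_n <- vapply(nets, nrow, integer(1L))
  node_n <- vapply(nets, function(x) length(union(x$gene_a, x$gene_b)), integer(1L))
  first_gene <- vapply(nets, function(x) min(c(x$gene_a, x$gene_b)), character(1L))
  ord <- order(-edge_n, -node_n, first_gene)
  unname(nets[ord])
}
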