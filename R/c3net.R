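#' Network edge-list constructor
#'
#' Networks are tibbles with one row per undirected edge and columns
#' `gene_a`, `gene_b` (with `gene_a < gene_b` lexicographically), `mi`
#' (edge weight in nats), `rank_a`/`rank_b` (the row-wise descending rank
#' of the pair within the row of `gene_a` / `gene_b` of the source MI
#' matrix) and `category` (one of tnet, cnet, test_difnet, control_difnet,
#' common, undecided_test).
#'
#' @param gene_a,gene_b Character vectors of endpoint identifiers.
#' @param mi Numeric edge weights.
#' @param rank_a,rank_b Integer row ranks per direction.
#' @param category Single category label.
#' @return A network tibble sorted by descending `mi`, then pair.
#' @keywords internal
new_network <- function(gene_a = character(), gene_b = character(),
                        mi = numeric(), rank_a = integer(),
                        rank_b = integer(), category = character()) {
  swap <- gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  ra <- ifelse(swap, rank_b, rank_a)
  rb <- ifelse(swap, rank_a, rank_b)
  tibble::tibble(
    gene_a = as.character(a),
    gene_b = as.character(b),
    mi = as.numeric(mi),
    rank_a = as.integer(ra),
    rank_b = as.integer(rb),
    category = if (length(gene_a)) as.character(category) else character()
  ) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$mi), .data$gene_a, .data$gene_b)
}

#' Conservative causal core network inference
#'
#' The C3NET rule: entries of the MI matrix below `threshold` are treated
#' as non-significant; every gene with at least one significant entry
#' contributes one edge, to its maximum-MI partner (ties broken towards
#' the lexicographically smallest partner identifier). The union of these
#' picks, deduplicated as undirected pairs, is the network, so the edge
#' count never exceeds the gene count. Genes whose whole row is
#' non-significant stay isolated — the method deliberately recovers only
#' the strongest "causal core" of the underlying interaction structure.
#'
#' @param mi Symmetric MI matrix with gene dimnames ([mi_matrix()]).
#' @param threshold Non-negative MI significance cut-off
#'   ([significance_threshold()] or a user-fixed value).
#' @param category Category label stored on the edges (default `"tnet"`).
#' @return A network tibble (see [new_network()] for columns).
#' @examples
#' mi <- matrix(c(0, .9, .2, .9, 0, .5, .2, .5, 0), 3,
#'   dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
#' )
#' c3net(mi, threshold = 0.3) # edges g1-g2 and g2-g3
#' @export
c3net <- function(mi, threshold = 0, category = "tnet") {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi), !is.null(rownames(mi)))
  if (threshold < 0) stop("threshold must be >= 0.", call. = FALSE)
  g <- nrow(mi)
  if (g < 2L) stop("Need at least 2 genes.", call. = FALSE)
  genes <- rownames(mi)
  rk <- rank_rows(mi)

  sig <- mi
  sig[sig < threshold] <- 0
  diag(sig) <- 0

  ia <- integer(); ib <- integer()
  for (i in seq_len(g)) {
    row <- sig[i, ]
    row[i] <- 0
    mx <- max(row)
    if (mx > 0) {
      # deterministic tie-break: smallest partner identifier
      cand <- which(row == mx)
      j <- cand[order(genes[cand])][1L]
      ia <- c(ia, i); ib <- c(ib, j)
    }
  }
  if (length(ia) == 0L) return(new_network(category = category))
  new_network(
    gene_a = genes[ia], gene_b = genes[ib],
    mi = mi[cbind(ia, ib)],
    rank_a = rk[cbind(ia, ib)],
    rank_b = rk[cbind(ib, ia)],
    category = category
  )
}
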