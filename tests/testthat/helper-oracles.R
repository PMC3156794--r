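# Independent brute-force oracles and small fixture builders. These
# re-derive every rule with explicit loops so they share no code path with
# the implementation.

expr_from_matrix <- function(vals, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(vals)))
  out <- tibble::as_tibble(as.data.frame(vals), .name_repair = "minimal")
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(gene = genes), out)
}

random_mi_matrix <- function(g, seed) {
  set.seed(seed)
  m <- matrix(0, g, g)
  m[upper.tri(m)] <- stats::runif(g * (g - 1) / 2)
  m <- m + t(m)
  genes <- sprintf("g%02d", seq_len(g))
  dimnames(m) <- list(genes, genes)
  m
}

# per-gene maximum among significant MI entries, derived edge by edge
oracle_c3net <- function(mi, threshold) {
  genes <- rownames(mi)
  g <- nrow(mi)
  picked <- character()
  for (i in seq_len(g)) {
    best_j <- NA_integer_
    best <- 0
    for (j in seq_len(g)) {
      if (j == i) next
      v <- mi[i, j]
      if (v < threshold || v <= 0) next
      if (v > best || (v == best && !is.na(best_j) && genes[j] < genes[best_j])) {
        best <- v
        best_j <- j
      }
    }
    if (!is.na(best_j)) {
      pair <- sort(c(genes[i], genes[best_j]))
      picked <- c(picked, paste(pair[1], pair[2]))
    }
  }
  sort(unique(picked))
}

net_pairs <- function(net) {
  if (nrow(net) == 0) return(character())
  sort(paste(net$gene_a, net$gene_b))
}

# four AND-ed strict clauses evaluated one edge at a time
oracle_difnet <- function(net, other_mi, other_rank, rankdif, mi_rate) {
  keep <- character()
  for (e in seq_len(nrow(net))) {
    a <- net$gene_a[e]; b <- net$gene_b[e]
    c1 <- other_rank[a, b] > rankdif
    c2 <- other_mi[a, b] < mi_rate * max(other_mi[a, ])
    c3 <- other_rank[b, a] > rankdif
    c4 <- other_mi[b, a] < mi_rate * max(other_mi[b, ])
    if (c1 && c2 && c3 && c4) keep <- c(keep, paste(a, b))
  }
  sort(keep)
}

# OR over two per-direction (rank AND MI) conjunctions
oracle_common <- function(net, other_mi, other_rank, rankdif_common, mi_rate_common) {
  keep <- character()
  for (e in seq_len(nrow(net))) {
    a <- net$gene_a[e]; b <- net$gene_b[e]
    dir_a <- (other_rank[a, b] < rankdif_common) &&
      (other_mi[a, b] > mi_rate_common * max(other_mi[a, ]))
    dir_b <- (other_rank[b, a] < rankdif_common) &&
      (other_mi[b, a] > mi_rate_common * max(other_mi[b, ]))
    if (dir_a || dir_b) keep <- c(keep, paste(a, b))
  }
  sort(keep)
}

# a network over the genes of an MI matrix: random unordered pairs with
# ranks looked up from the matrix's own rank structure
random_network_from <- function(mi, n_edges, seed) {
  set.seed(seed)
  g <- nrow(mi)
  genes <- rownames(mi)
  rk <- dc3net::rank_rows(mi)
  pairs <- t(utils::combn(g, 2))
  take <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), , drop = FALSE]
  tibble::tibble(
    gene_a = genes[take[, 1]], gene_b = genes[take[, 2]],
    mi = mi[take], rank_a = rk[take],
    rank_b = rk[take[, c(2, 1), drop = FALSE]],
    category = "tnet"
  )
}
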