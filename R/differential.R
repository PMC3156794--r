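#' Decision-filter parameters for differential network inference
#'
#' Bundles the cut-offs of the rank/MI decision filter and the significance
#' settings of the conservative causal core step.
#'
#' * `rankdif` — an edge is condition-specific only if its rank in the
#'   other condition's row-ranked MI matrix is numerically greater than
#'   `rankdif` in **both** directions. Default 2000, the published
#'   case-study setting for a ~12,000-gene dataset; scale it down with the
#'   gene count (see the methods vignette).
#' * `mi_rate` — the MI cut-off for a row is `mi_rate` times that row's
#'   maximum MI in the other condition; the edge's MI there must fall
#'   below it in both directions. Default 0.6.
#' * `rankdif_common`, `mi_rate_common` — the common-network counterparts,
#'   with the comparisons reversed (rank smaller than, MI greater than) and
#'   required in only one direction. Defaults 200 and 0.85.
#' * `common_absolute` — interpret `mi_rate_common` as an absolute MI value
#'   instead of a rate (default `FALSE`, the rate reading).
#' * `extended_common` — also add to the common network the Cnet edges that
#'   look strong in the test condition (the symmetric extra step).
#' * `alpha`, `B`, `mi_threshold` — significance level and permutation
#'   rounds for [significance_threshold()]; a non-`NULL` `mi_threshold`
#'   bypasses the permutation test with a fixed cut-off.
#'
#' @param rankdif Positive integer rank cut-off for difnets.
#' @param mi_rate Fraction in (0, 1] defining the difnet MI cut-off.
#' @param rankdif_common Positive integer rank cut-off for the common net.
#' @param mi_rate_common Fraction in (0, 1] (or absolute MI when
#'   `common_absolute`) for the common net.
#' @param common_absolute Flag, absolute-MI reading of `mi_rate_common`.
#' @param extended_common Flag, add the Cnet-vs-test common edges.
#' @param alpha Significance level for the permutation null.
#' @param B Permutation rounds.
#' @param mi_threshold Optional fixed MI threshold overriding the
#'   permutation test.
#' @return A `dc3net_params` list.
#' @export
dc3net_params <- function(rankdif = 2000L, mi_rate = 0.6,
                          rankdif_common = 200L, mi_rate_common = 0.85,
                          common_absolute = FALSE, extended_common = FALSE,
                          alpha = 0.01, B = 30L, mi_threshold = NULL) {
  stopifnot(
    rankdif >= 1L, rankdif_common >= 1L,
    mi_rate > 0, mi_rate <= 1,
    mi_rate_common > 0, common_absolute || mi_rate_common <= 1,
    alpha > 0, alpha < 1, B >= 1L,
    is.null(mi_threshold) || mi_threshold >= 0
  )
  structure(
    list(
      rankdif = as.integer(rankdif), mi_rate = mi_rate,
      rankdif_common = as.integer(rankdif_common),
      mi_rate_common = mi_rate_common,
      common_absolute = isTRUE(common_absolute),
      extended_common = isTRUE(extended_common),
      alpha = alpha, B = as.integer(B), mi_threshold = mi_threshold
    ),
    class = "dc3net_params"
  )
}

check_net_genes <- function(net, other_mi) {
  genes <- union(net$gene_a, net$gene_b)
  missing <- setdiff(genes, rownames(other_mi))
  if (length(missing)) {
    stop(sprintf(
      "Genes absent from the other condition's MI matrix: %s. Align conditions first (keep_all = FALSE).",
      paste(utils::head(missing, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Condition-specific (difnet) decision filter
#'
#' Keeps an edge (gA, gB) of a condition's network only when its signal in
#' the *other* condition is weak by four simultaneous strict conditions:
#' its rank in row gA of the other rank matrix is greater than `rankdif`
#' (1), its MI there is below `mi_rate` times row gA's maximum MI (2), and
#' the same two tests hold in the gB direction (3, 4). All four must hold;
#' boundary equality fails. Applied to the test network against the
#' control matrices it yields the test difnet (the "disease network");
#' with the roles swapped, the control difnet.
#'
#' @param net Network tibble (edges of Tnet or Cnet).
#' @param other_mi MI matrix of the other condition.
#' @param other_rank Row-wise descending rank matrix of `other_mi`
#'   ([rank_rows()]).
#' @param rankdif,mi_rate Cut-offs; see [dc3net_params()].
#' @param category Category label for surviving edges.
#' @return The filtered network tibble.
#' @export
difnet_filter <- function(net, other_mi, other_rank,
                          rankdif = 2000L, mi_rate = 0.6,
                          category = "test_difnet") {
  if (nrow(net) == 0L) return(dplyr::mutate(net, category = character(0)))
  check_net_genes(net, other_mi)
  row_max <- apply_row_max(other_mi)
  ia <- match(net$gene_a, rownames(other_mi))
  ib <- match(net$gene_b, rownames(other_mi))
  mi_ab <- other_mi[cbind(ia, ib)]
  mi_ba <- other_mi[cbind(ib, ia)]
  keep <- (other_rank[cbind(ia, ib)] > rankdif) &
    (mi_ab < mi_rate * row_max[ia]) &
    (other_rank[cbind(ib, ia)] > rankdif) &
    (mi_ba < mi_rate * row_max[ib])
  out <- net[keep, , drop = FALSE]
  out$category <- rep(category, nrow(out))
  out
}

#' Common-network decision filter
#'
#' The mirror image of [difnet_filter()]: an edge of the test network is
#' kept when its signal in the other condition is *strong* — its rank
#' there is smaller than `rankdif_common` **and** its MI exceeds
#' `mi_rate_common` times the row maximum — in at least one of the two
#' directions (a logical OR over the per-direction conjunctions). With
#' `common_absolute`, the MI clause compares against `mi_rate_common`
#' directly instead of a rate of the row maximum.
#'
#' @inheritParams difnet_filter
#' @param rankdif_common,mi_rate_common,common_absolute Cut-offs; see
#'   [dc3net_params()].
#' @return The filtered network tibble with category `"common"`.
#' @export
common_filter <- function(net, other_mi, other_rank,
                          rankdif_common = 200L, mi_rate_common = 0.85,
                          common_absolute = FALSE) {
  if (nrow(net) == 0L) return(dplyr::mutate(net, category = character(0)))
  check_net_genes(net, other_mi)
  row_max <- apply_row_max(other_mi)
  ia <- match(net$gene_a, rownames(other_mi))
  ib <- match(net$gene_b, rownames(other_mi))
  cut_a <- if (common_absolute) mi_rate_common else mi_rate_common * row_max[ia]
  cut_b <- if (common_absolute) mi_rate_common else mi_rate_common * row_max[ib]
  dir_a <- (other_rank[cbind(ia, ib)] < rankdif_common) & (other_mi[cbind(ia, ib)] > cut_a)
  dir_b <- (other_rank[cbind(ib, ia)] < rankdif_common) & (other_mi[cbind(ib, ia)] > cut_b)
  out <- net[dir_a | dir_b, , drop = FALSE]
  out$category <- rep("common", nrow(out))
  out
}

apply_row_max <- function(mi) {
  mx <- apply(mi, 1L, max)
  names(mx) <- rownames(mi)
  mx
}

#' Run the full differential network pipeline
#'
#' Orchestrates the whole analysis for a test/control expression pair:
#' gene alignment, per-gene copula transformation, Gaussian MI matrices and
#' their row-rank matrices, permutation significance thresholds, the
#' conservative causal core networks of each condition (Tnet, Cnet), and
#' the rank/MI decision filters producing the test difnet, control difnet
#' and common network. Tnet edges passing neither the difnet nor the
#' common filter land in `undecided_test` — the deliberate gap that keeps
#' decisions away from the cut-off boundaries.
#'
#' @param test,control Expression tibbles (raw, not yet copula-transformed).
#' @param params A [dc3net_params()] list.
#' @param keep_all Passed to [align_conditions()].
#' @param seed Integer seed for the significance permutation test.
#' @return A `dc3net` object: a list with network tibbles `tnet`, `cnet`,
#'   `test_difnet`, `control_difnet`, `common`, `undecided_test`, the
#'   `params`, the per-condition `thresholds`, the alignment `report` and
#'   the shared `genes`. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @examples
#' sim <- simulate_condition_pair(n_genes = 20, seed = 1)
#' fit <- run_dc3net(sim$test, sim$control,
#'   params = dc3net_params(rankdif = 4, rankdif_common = 2, B = 5), seed = 1
#' )
#' glance(fit)
#' @export
run_dc3net <- function(test, control, params = dc3net_params(),
                       keep_all = FALSE, seed = 1L) {
  stopifnot(inherits(params, "dc3net_params"))
  al <- align_conditions(test, control, keep_all = keep_all)
  tc <- copula_transform(al$test)
  cc <- copula_transform(al$control)
  mi_t <- mi_matrix(tc)
  mi_c <- mi_matrix(cc)
  rk_t <- rank_rows(mi_t)
  rk_c <- rank_rows(mi_c)
  thr_t <- params$mi_threshold %||%
    significance_threshold(tc, alpha = params$alpha, B = params$B, seed = seed)
  thr_c <- params$mi_threshold %||%
    significance_threshold(cc, alpha = params$alpha, B = params$B, seed = seed)
  tnet <- c3net(mi_t, thr_t, category = "tnet")
  cnet <- c3net(mi_c, thr_c, category = "cnet")
  test_difnet <- difnet_filter(tnet, mi_c, rk_c,
    rankdif = params$rankdif, mi_rate = params$mi_rate, category = "test_difnet"
  )
  control_difnet <- difnet_filter(cnet, mi_t, rk_t,
    rankdif = params$rankdif, mi_rate = params$mi_rate, category = "control_difnet"
  )
  common <- common_filter(tnet, mi_c, rk_c,
    rankdif_common = params$rankdif_common,
    mi_rate_common = params$mi_rate_common,
    common_absolute = params$common_absolute
  )
  if (params$extended_common) {
    extra <- common_filter(cnet, mi_t, rk_t,
      rankdif_common = params$rankdif_common,
      mi_rate_common = params$mi_rate_common,
      common_absolute = params$common_absolute
    )
    common <- dplyr::bind_rows(common, extra) |>
      dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
      dplyr::arrange(dplyr::desc(.data$mi), .data$gene_a, .data$gene_b)
  }
  decided <- dplyr::bind_rows(test_difnet, common)
  undecided <- dplyr::anti_join(tnet, decided, by = c("gene_a", "gene_b"))
  undecided$category <- rep("undecided_test", nrow(undecided))

  structure(
    list(
      tnet = tnet, cnet = cnet,
      test_difnet = test_difnet, control_difnet = control_difnet,
      common = common, undecided_test = undecided,
      params = params,
      thresholds = c(test = unname(thr_t), control = unname(thr_c)),
      report = al$report,
      genes = expr_genes(al$test),
      seed = as.integer(seed)
    ),
    class = "dc3net"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dc3net <- function(x, ...) {
  cat("Differential C3NET analysis\n")
  cat(sprintf("  genes: %d (shared)\n", length(x$genes)))
  cat(sprintf(
    "  MI thresholds (nats): test %.4f, control %.4f\n",
    x$thresholds[["test"]], x$thresholds[["control"]]
  ))
  cat(sprintf(
    "  edges: tnet %d, cnet %d | test difnet %d, control difnet %d, common %d, undecided %d\n",
    nrow(x$tnet), nrow(x$cnet), nrow(x$test_difnet),
    nrow(x$control_difnet), nrow(x$common), nrow(x$undecided_test)
  ))
  cat(sprintf(
    "  filter: rankdif %d, mi_rate %.2f | common: rankdif %d, mi_rate %.2f%s\n",
    x$params$rankdif, x$params$mi_rate, x$params$rankdif_common,
    x$params$mi_rate_common,
    if (x$params$common_absolute) " (absolute)" else ""
  ))
  invisible(x)
}
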