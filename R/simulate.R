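#' Simulate a two-condition expression pair with known interactions
#'
#' Generates test and control expression tables over one gene universe
#' with planted pairwise dependencies of known location: `n_common` edges
#' active in both conditions, `n_test_only` active only in the test
#' condition, and `n_control_only` only in the control condition. The
#' union of the three edge sets is drawn from a random spanning tree of
#' the gene universe, so each condition's active edge set is a forest and
#' "direct interaction" ground truth is unambiguous (indirect correlation
#' still arises through shared parents). Every gene starts as standard
#' normal noise; each active edge, visited parent-to-child along the
#' attachment order, adds `effect * f(parent)` plus `N(0, noise_sd)` noise
#' to the child, where `f` is the identity for linear edges and the
#' centred quadratic `x^2 - mean(x^2)` for a `nonlinear_fraction` of edges
#' (the same edges in both conditions). Deterministic given `seed`.
#'
#' @param n_genes Number of genes (>= 3).
#' @param n_samples_test,n_samples_control Samples per condition (>= 10).
#' @param n_common,n_test_only,n_control_only Planted edge counts; their
#'   sum must be at most `n_genes - 1`.
#' @param effect Linear/quadratic effect weight of parent on child.
#' @param noise_sd Standard deviation of the per-edge transmission noise.
#' @param nonlinear_fraction Fraction of planted edges given the quadratic
#'   dependency, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `test` and `control` expression tibbles and
#'   `truth`, a tibble of planted edges with columns `gene_a`, `gene_b`
#'   (sorted pairs), `condition` (`common`/`test_only`/`control_only`) and
#'   `nonlinear`, plus a `params` attribute recording the generator
#'   settings.
#' @examples
#' sim <- simulate_condition_pair(n_genes = 30, seed = 7)
#' dplyr::count(sim$truth, condition)
#' @export
simulate_condition_pair <- function(n_genes = 50L, n_samples_test = 100L,
                                    n_samples_control = 100L,
                                    n_common = 15L, n_test_only = 10L,
                                    n_control_only = 10L,
                                    effect = 1.0, noise_sd = 0.5,
                                    nonlinear_fraction = 0.2, seed = 1L) {
  n_genes <- as.integer(n_genes)
  total <- n_common + n_test_only + n_control_only
  if (n_genes < 3L) stop("Need at least 3 genes.", call. = FALSE)
  if (n_samples_test < 10L || n_samples_control < 10L) {
    stop("Need at least 10 samples per condition.", call. = FALSE)
  }
  if (any(c(n_common, n_test_only, n_control_only) < 0L)) {
    stop("Edge counts must be non-negative.", call. = FALSE)
  }
  if (total > n_genes - 1L) {
    stop(sprintf(
      "Requested %d edges but a forest over %d genes holds at most %d.",
      total, n_genes, n_genes - 1L
    ), call. = FALSE)
  }
  if (nonlinear_fraction < 0 || nonlinear_fraction > 1) {
    stop("nonlinear_fraction must be in [0, 1].", call. = FALSE)
  }
  rng <- local_rng(seed)
  genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))

  # random spanning tree by random attachment; attachment order is the
  # topological order used when propagating effects
  ord <- rng$sample_int(n_genes)
  parent_of <- integer(n_genes) # position in `ord` of each child's parent
  for (k in 2:n_genes) parent_of[k] <- rng$sample_int(k - 1L, 1L)
  tree_child <- 2:n_genes # positions in ord

  pick <- rng$sample_int(n_genes - 1L, total)
  lab <- rep(c("common", "test_only", "control_only"),
    times = c(n_common, n_test_only, n_control_only)
  )
  n_nl <- round(nonlinear_fraction * total)
  nl_idx <- if (n_nl > 0) rng$sample_int(total, n_nl) else integer()

  edge_child_pos <- tree_child[pick] # position in ord
  edge_parent_pos <- parent_of[edge_child_pos]
  truth <- new_truth_tibble(
    parent = genes[ord[edge_parent_pos]],
    child = genes[ord[edge_child_pos]],
    condition = lab,
    nonlinear = seq_len(total) %in% nl_idx
  )

  f_quad <- function(x) x^2 - mean(x^2)
  gen_condition <- function(n_samples, active) {
    vals <- matrix(rng$rnorm(n_genes * n_samples), n_genes, n_samples)
    # iterate children in topological (attachment) order
    act <- active[order(active$child_pos), , drop = FALSE]
    for (e in seq_len(nrow(act))) {
      p <- act$parent_pos[e]
      ch <- act$child_pos[e]
      src <- if (act$nonlinear[e]) f_quad(vals[p, ]) else vals[p, ]
      vals[ch, ] <- vals[ch, ] + effect * src + rng$rnorm(n_samples, 0, noise_sd)
    }
    rownames(vals) <- genes[ord]
    vals[match(genes, genes[ord]), , drop = FALSE]
  }
  edge_pos <- tibble::tibble(
    parent_pos = edge_parent_pos, child_pos = edge_child_pos,
    condition = lab, nonlinear = seq_len(total) %in% nl_idx
  )
  test_vals <- gen_condition(
    n_samples_test,
    edge_pos[edge_pos$condition %in% c("common", "test_only"), ]
  )
  control_vals <- gen_condition(
    n_samples_control,
    edge_pos[edge_pos$condition %in% c("common", "control_only"), ]
  )
  colnames(test_vals) <- sprintf("t%d", seq_len(n_samples_test))
  colnames(control_vals) <- sprintf("c%d", seq_len(n_samples_control))

  attr(truth, "params") <- list(
    n_genes = n_genes, n_samples_test = n_samples_test,
    n_samples_control = n_samples_control, n_common = n_common,
    n_test_only = n_test_only, n_control_only = n_control_only,
    effect = effect, noise_sd = noise_sd,
    nonlinear_fraction = nonlinear_fraction, seed = seed
  )
  list(
    test = expr_tibble(test_vals),
    control = expr_tibble(control_vals),
    truth = truth
  )
}

new_truth_tibble <- function(parent, child, condition, nonlinear) {
  swap <- parent > child
  tibble::tibble(
    gene_a = ifelse(swap, child, parent),
    gene_b = ifelse(swap, parent, child),
    condition = condition,
    nonlinear = nonlinear
  ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Planted edges active in a given condition
#'
#' @param truth Truth tibble from [simulate_condition_pair()].
#' @param condition `"test"` or `"control"`.
#' @return Tibble of the active edges (`gene_a`, `gene_b`).
#' @export
active_truth_edges <- function(truth, condition = c("test", "control")) {
  condition <- match.arg(condition)
  keep <- switch(condition,
    test = c("common", "test_only"),
    control = c("common", "control_only")
  )
  truth[truth$condition %in% keep, c("gene_a", "gene_b")]
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Score the recovery of planted edges
#'
#' Compares an inferred network against a ground-truth edge set as
#' unordered pairs. Precision and recall follow the convention that an
#' empty comparison set scores 1 (no false claims possible); F1 is the
#' harmonic mean (0 when both are 0).
#'
#' @param inferred Network tibble (or any data frame with `gene_a`,
#'   `gene_b`).
#' @param truth_edges Data frame with `gene_a`, `gene_b` columns.
#' @return One-row tibble: `true_positive`, `false_positive`,
#'   `false_negative`, `precision`, `recall`, `f1`.
#' @export
score_recovery <- function(inferred, truth_edges) {
  inf_keys <- unique(pair_key(inferred$gene_a, inferred$gene_b))
  tru_keys <- unique(pair_key(truth_edges$gene_a, truth_edges$gene_b))
  tp <- length(intersect(inf_keys, tru_keys))
  fp <- length(setdiff(inf_keys, tru_keys))
  fn <- length(setdiff(tru_keys, inf_keys))
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(
    true_positive = tp, false_positive = fp, false_negative = fn,
    precision = precision, recall = recall, f1 = f1
  )
}
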