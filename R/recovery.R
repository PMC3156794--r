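#' Synthetic recovery study of the differential pipeline
#'
#' Runs the full pipeline on independently simulated two-condition
#' datasets and scores how well the planted structure is recovered. For
#' each seed it simulates a condition pair, runs the analysis, and
#' records: the fraction of test-only planted edges recovered in the test
#' difnet and (spuriously) in the control difnet, the test-network recall
#' and precision against all edges active in the test condition, and the
#' recall of a matched `effect = 0` null generator run (same seed, no
#' planted signal) as the noise floor.
#'
#' Defaults describe the reference study: 50 genes, 100 samples per
#' condition, 15 common + 10 test-only + 10 control-only edges, effect
#' 1.0, transmission noise 0.5, 20% quadratic edges. The filter cut-offs
#' default to the published settings rescaled to the generator's gene
#' count (see the methods vignette): `rankdif = 8`, `rankdif_common = 2`,
#' `mi_rate = 0.6`, `mi_rate_common = 0.85`.
#'
#' @param seeds Integer vector of generator seeds (one row per seed).
#' @param n_genes,n_samples,n_common,n_test_only,n_control_only,effect,noise_sd,nonlinear_fraction
#'   Generator settings, see [simulate_condition_pair()].
#' @param params [dc3net_params()] for the analysis.
#' @return A tibble with one row per seed: `frac_test_only_in_test_difnet`,
#'   `frac_test_only_in_control_difnet`, `tnet_recall`, `tnet_precision`,
#'   `null_tnet_recall`, and the difnet/common edge counts.
#' @export
recovery_study <- function(seeds = 1:20, n_genes = 50L, n_samples = 100L,
                           n_common = 15L, n_test_only = 10L,
                           n_control_only = 10L, effect = 1.0,
                           noise_sd = 0.5, nonlinear_fraction = 0.2,
                           params = dc3net_params(
                             rankdif = 8L, rankdif_common = 2L,
                             alpha = 0.01, B = 10L
                           )) {
  purrr::map_dfr(seeds, function(seed) {
    sim <- simulate_condition_pair(
      n_genes = n_genes, n_samples_test = n_samples,
      n_samples_control = n_samples, n_common = n_common,
      n_test_only = n_test_only, n_control_only = n_control_only,
      effect = effect, noise_sd = noise_sd,
      nonlinear_fraction = nonlinear_fraction, seed = seed
    )
    fit <- run_dc3net(sim$test, sim$control, params = params, seed = seed)
    test_only <- sim$truth[sim$truth$condition == "test_only", ]
    active <- active_truth_edges(sim$truth, "test")
    sc_tnet <- score_recovery(fit$tnet, active)

    # matched null: same generator call with the signal switched off
    null_sim <- simulate_condition_pair(
      n_genes = n_genes, n_samples_test = n_samples,
      n_samples_control = n_samples, n_common = n_common,
      n_test_only = n_test_only, n_control_only = n_control_only,
      effect = 0, noise_sd = noise_sd,
      nonlinear_fraction = nonlinear_fraction, seed = seed
    )
    null_tc <- copula_transform(null_sim$test)
    null_thr <- params$mi_threshold %||%
      significance_threshold(null_tc, alpha = params$alpha, B = params$B, seed = seed)
    null_tnet <- c3net(mi_matrix(null_tc), null_thr)
    null_sc <- score_recovery(null_tnet, active_truth_edges(null_sim$truth, "test"))

    tibble::tibble(
      seed = seed,
      frac_test_only_in_test_difnet =
        score_recovery(fit$test_difnet, test_only)$recall,
      frac_test_only_in_control_difnet =
        score_recovery(fit$control_difnet, test_only)$recall,
      tnet_recall = sc_tnet$recall,
      tnet_precision = sc_tnet$precision,
      null_tnet_recall = null_sc$recall,
      n_tnet = nrow(fit$tnet),
      n_test_difnet = nrow(fit$test_difnet),
      n_control_difnet = nrow(fit$control_difnet),
      n_common_net = nrow(fit$common)
    )
  })
}
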