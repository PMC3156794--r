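# a 5-gene toy where the other condition's matrices are set by hand
toy_other <- function(mi_ab) {
  genes <- c("A", "B", "C", "D", "E")
  mi <- matrix(0.2, 5, 5, dimnames = list(genes, genes))
  diag(mi) <- 0
  mi["A", "B"] <- mi["B", "A"] <- mi_ab
  mi["A", "C"] <- mi["C", "A"] <- 1.0 # row maxima for A
  mi["B", "D"] <- mi["D", "B"] <- 1.0 # and for B
  mi
}

toy_net <- function() {
  tibble::tibble(
    gene_a = "A", gene_b = "B", mi = 0.7,
    rank_a = 1L, rank_b = 1L, category = "tnet"
  )
}

test_that("difnet filter keeps an edge only when all four conditions hold", {
  net <- toy_net()
  other <- toy_other(0.1) # (A,B) weak in the other condition
  rk <- rank_rows(other)
  # (A,B) ranks: row A has 1.0 > 0.2 = ... > 0.1, so rank of B is worst (4)
  expect_equal(rk["A", "B"], 4L)
  kept <- difnet_filter(net, other, rk, rankdif = 3, mi_rate = 0.6)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$category, "test_difnet")

  # MI clause fails: 0.7 >= 0.6 * 1.0 in both rows
  other2 <- toy_other(0.7)
  rk2 <- rank_rows(other2)
  expect_equal(nrow(difnet_filter(net, other2, rk2, rankdif = 1, mi_rate = 0.6)), 0L)

  # rank clause fails: rankdif too strict
  expect_equal(nrow(difnet_filter(net, other, rk, rankdif = 4, mi_rate = 0.6)), 0L)
})

test_that("common filter needs strong rank AND MI in at least one direction", {
  net <- toy_net()
  genes <- c("A", "B", "C", "D", "E")
  other <- matrix(0.1, 5, 5, dimnames = list(genes, genes))
  diag(other) <- 0
  other["A", "B"] <- other["B", "A"] <- 0.9
  other["B", "D"] <- other["D", "B"] <- 1.0 # B's row max is D, not A
  rk <- rank_rows(other)
  # direction A: rank 1 and 0.9 > 0.85 * 0.9 (row max of A is 0.9) -> kept
  kept <- common_filter(net, other, rk, rankdif_common = 2, mi_rate_common = 0.85)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$category, "common")

  # rank 1 but MI only 0.8 of the row max, other direction fails rank
  other["A", "B"] <- other["B", "A"] <- 0.9
  other["A", "C"] <- other["C", "A"] <- 1.125 # row max A; 0.9 = 0.8 * 1.125
  rk <- rank_rows(other)
  expect_equal(rk["A", "B"], 2L)
  expect_equal(nrow(common_filter(net, other, rk, rankdif_common = 2, mi_rate_common = 0.85)), 0L)
})

test_that("boundary equality fails the strict comparisons", {
  net <- toy_net()
  genes <- c("A", "B", "C", "D", "E")
  other <- matrix(0.1, 5, 5, dimnames = list(genes, genes))
  diag(other) <- 0
  other["A", "B"] <- other["B", "A"] <- 0.5 # rank 1 in both rows
  rk <- rank_rows(other)
  # MI equals the row max: 0.5 > 1.0 * 0.5 is false
  expect_equal(nrow(common_filter(net, other, rk, rankdif_common = 5, mi_rate_common = 1)), 0L)
  # rank equals rankdif: 1 < 1 is false
  expect_equal(nrow(common_filter(net, other, rk, rankdif_common = 1, mi_rate_common = 0.5)), 0L)
})

test_that("filters agree with the independent Boolean oracle", {
  for (seed in 1:200) {
    g <- 5 + (seed %% 8)
    set.seed(seed + 5000)
    other <- random_mi_matrix(g, seed + 5000)
    rk <- rank_rows(other)
    net <- random_network_from(other, n_edges = g, seed = seed)
    rankdif <- sample(1:(g - 1), 1)
    mi_rate <- stats::runif(1, 0.2, 1)
    got <- difnet_filter(net, other, rk, rankdif = rankdif, mi_rate = mi_rate)
    expect_identical(net_pairs(got), oracle_difnet(net, other, rk, rankdif, mi_rate))
    rc <- sample(1:(g - 1), 1)
    mc <- stats::runif(1, 0.2, 1)
    gotc <- common_filter(net, other, rk, rankdif_common = rc, mi_rate_common = mc)
    expect_identical(net_pairs(gotc), oracle_common(net, other, rk, rc, mc))
  }
})

test_that("identical conditions yield empty difnets and common == Tnet", {
  sim <- simulate_condition_pair(n_genes = 25, n_common = 10, n_test_only = 0,
                                 n_control_only = 0, seed = 42)
  fit <- run_dc3net(sim$test, sim$test, params = dc3net_params(B = 10), seed = 3)
  expect_equal(nrow(fit$test_difnet), 0L)
  expect_equal(nrow(fit$control_difnet), 0L)
  expect_equal(net_pairs(fit$tnet), net_pairs(fit$cnet))
  expect_equal(net_pairs(fit$common), net_pairs(fit$tnet))
  expect_equal(nrow(fit$undecided_test), 0L)
})

test_that("difnet shrinks as rankdif grows or mi_rate shrinks", {
  sim <- simulate_condition_pair(seed = 11)
  fit <- run_dc3net(sim$test, sim$control,
    params = dc3net_params(rankdif = 8, rankdif_common = 2, B = 10), seed = 1
  )
  al <- align_conditions(sim$test, sim$control)
  mi_c <- mi_matrix(copula_transform(al$control))
  rk_c <- rank_rows(mi_c)
  sizes_rank <- vapply(c(2, 8, 20, 45), function(rd) {
    nrow(difnet_filter(fit$tnet, mi_c, rk_c, rankdif = rd, mi_rate = 0.6))
  }, numeric(1))
  expect_true(all(diff(sizes_rank) <= 0))
  sizes_rate <- vapply(c(0.9, 0.6, 0.3), function(mr) {
    nrow(difnet_filter(fit$tnet, mi_c, rk_c, rankdif = 8, mi_rate = mr))
  }, numeric(1))
  expect_true(all(diff(sizes_rate) <= 0))
})

test_that("outputs are subsets of their source network with identical weights", {
  sim <- simulate_condition_pair(seed = 2)
  fit <- run_dc3net(sim$test, sim$control,
    params = dc3net_params(rankdif = 8, rankdif_common = 2, B = 10), seed = 1
  )
  for (nm in c("test_difnet", "common", "undecided_test")) {
    sub <- fit[[nm]]
    j <- dplyr::inner_join(sub, fit$tnet, by = c("gene_a", "gene_b"), suffix = c("", ".t"))
    expect_equal(nrow(j), nrow(sub))
    expect_equal(j$mi, j$mi.t)
  }
  j <- dplyr::inner_join(fit$control_difnet, fit$cnet, by = c("gene_a", "gene_b"), suffix = c("", ".c"))
  expect_equal(nrow(j), nrow(fit$control_difnet))

  # difnet, common and undecided partition Tnet when rankdif_common <= rankdif
  expect_length(intersect(net_pairs(fit$test_difnet), net_pairs(fit$common)), 0L)
  expect_setequal(
    c(net_pairs(fit$test_difnet), net_pairs(fit$common), net_pairs(fit$undecided_test)),
    net_pairs(fit$tnet)
  )
})

test_that("extended common network adds the Cnet-side strong edges", {
  sim <- simulate_condition_pair(seed = 13)
  p0 <- dc3net_params(rankdif = 8, rankdif_common = 2, B = 10)
  p1 <- dc3net_params(rankdif = 8, rankdif_common = 2, B = 10, extended_common = TRUE)
  fit0 <- run_dc3net(sim$test, sim$control, params = p0, seed = 1)
  fit1 <- run_dc3net(sim$test, sim$control, params = p1, seed = 1)
  expect_true(all(net_pairs(fit0$common) %in% net_pairs(fit1$common)))
  expect_gte(nrow(fit1$common), nrow(fit0$common))
})

test_that("parameter validation rejects out-of-range cut-offs", {
  expect_error(dc3net_params(rankdif = 0))
  expect_error(dc3net_params(mi_rate = 0))
  expect_error(dc3net_params(mi_rate = 1.2))
  expect_error(dc3net_params(alpha = 1))
  # absolute reading allows mi_rate_common > 1
  p <- dc3net_params(mi_rate_common = 2, common_absolute = TRUE)
  expect_true(p$common_absolute)
})

test_that("tidy, glance and autoplot summarise a fit", {
  sim <- simulate_condition_pair(n_genes = 20, n_common = 8, n_test_only = 5,
                                 n_control_only = 5, seed = 4)
  fit <- run_dc3net(sim$test, sim$control,
    params = dc3net_params(rankdif = 4, rankdif_common = 2, B = 5), seed = 1
  )
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(
    unique(td$category) |> setdiff(c("tnet", "cnet", "test_difnet", "control_difnet", "common", "undecided_test")),
    character()
  )
  expect_equal(nrow(tidy(fit, networks = "tnet")), nrow(fit$tnet))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_tnet, nrow(fit$tnet))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Differential C3NET")
})
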