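# hand-rolled Pearson correlation, kept independent of stats::cor
manual_cor <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

test_that("gaussian_mi matches the closed form -0.5 log(1 - r^2)", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    r <- manual_cor(x, y)
    expect_equal(gaussian_mi(x, y), -0.5 * log(1 - r^2), tolerance = 1e-12)
  }
})

test_that("gaussian_mi handles perfect correlation and zero variance", {
  x <- as.numeric(1:20)
  expect_equal(gaussian_mi(x, x), -0.5 * log(1e-12))
  expect_equal(gaussian_mi(x, -2 * x + 5), -0.5 * log(1e-12))
  expect_equal(gaussian_mi(x, rep(3, 20)), 0)
  expect_error(gaussian_mi(1:3, 1:4), "equal length")
  expect_error(gaussian_mi(1:2, 1:2), "at least 3")
})

test_that("mi_matrix is symmetric, non-negative, zero-diagonal", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- expr_from_matrix(matrix(rnorm(10 * 20), 10, 20))
    mi <- mi_matrix(copula_transform(m))
    expect_equal(mi, t(mi))
    expect_true(all(diag(mi) == 0))
    expect_true(all(mi >= 0) && all(is.finite(mi)))
  }
})

test_that("mi_matrix entries equal pairwise gaussian_mi and handle duplicates", {
  set.seed(1)
  vals <- matrix(rnorm(4 * 30), 4, 30)
  vals[2, ] <- vals[1, ] # duplicated probe
  m <- copula_transform(expr_from_matrix(vals))
  mi <- mi_matrix(m)
  v <- as.matrix(m[-1])
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(mi[i, j], gaussian_mi(v[i, ], v[j, ]))
    }
  }
  expect_equal(mi[1, 2], -0.5 * log(1e-12)) # clamped, finite
  expect_error(mi_matrix(m[1, ]), "at least 2 genes")
})

test_that("independent genes give small MI at large n", {
  set.seed(99)
  m <- copula_transform(expr_from_matrix(matrix(rnorm(3 * 1000), 3, 1000)))
  mi <- mi_matrix(m)
  expect_true(all(mi[upper.tri(mi)] < 0.05))
})

test_that("rank_rows ranks each row descending with competition ties", {
  mi <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  mi["a", c("b", "c", "d")] <- c(0.9, 0.2, 0.5)
  mi[, "a"] <- mi["a", ]
  mi["b", c("c", "d")] <- c(0.4, 0.4)
  mi[c("c", "d"), "b"] <- 0.4
  mi["c", "d"] <- mi["d", "c"] <- 0.4
  rk <- rank_rows(mi)
  expect_equal(unname(rk["a", c("b", "c", "d")]), c(1L, 3L, 2L))
  # row b off-diagonals 0.9, 0.4, 0.4: competition ranks 1, 2, 2
  expect_equal(unname(rk["b", c("a", "c", "d")]), c(1L, 2L, 2L))
  expect_equal(unname(diag(rk)), rep(4L, 4))

  all_tied <- matrix(0.4, 4, 4, dimnames = dimnames(mi))
  diag(all_tied) <- 0
  rk2 <- rank_rows(all_tied)
  expect_true(all(rk2[row(rk2) != col(rk2)] == 1L))

  two <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(rank_rows(two)[cbind(c(1, 2), c(2, 1))]), c(1L, 1L))
})

test_that("rank 1 attains the row maximum and ranks are order-isomorphic", {
  for (seed in 1:20) {
    mi <- random_mi_matrix(sample(5:12, 1), seed)
    rk <- rank_rows(mi)
    g <- nrow(mi)
    for (i in seq_len(g)) {
      off <- setdiff(seq_len(g), i)
      expect_equal(unname(mi[i, off][rk[i, off] == 1L][1]), max(mi[i, off]))
      ord <- order(-mi[i, off])
      expect_true(all(diff(rk[i, off][ord]) >= 0))
    }
  }
})

test_that("significance threshold is deterministic and monotone in alpha", {
  set.seed(3)
  m <- copula_transform(expr_from_matrix(matrix(rnorm(20 * 40), 20, 40)))
  t1 <- significance_threshold(m, alpha = 0.05, B = 5, seed = 11)
  t2 <- significance_threshold(m, alpha = 0.05, B = 5, seed = 11)
  expect_identical(t1, t2)
  t3 <- significance_threshold(m, alpha = 0.05, B = 5, seed = 12)
  expect_false(identical(t1, t3))

  alphas <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  thr <- vapply(alphas, function(a) significance_threshold(m, alpha = a, B = 5, seed = 1), numeric(1))
  expect_true(all(diff(thr) <= 0))
  expect_error(significance_threshold(m, alpha = 1.2, B = 5), "alpha")
})

test_that("duplicated genes exceed the permutation threshold", {
  set.seed(8)
  vals <- matrix(rnorm(10 * 50), 10, 50)
  vals[2, ] <- vals[1, ]
  m <- copula_transform(expr_from_matrix(vals))
  thr <- significance_threshold(m, alpha = 0.01, B = 100, seed = 4)
  mi <- mi_matrix(m)
  expect_gt(mi[1, 2], thr)
})

test_that("significance_threshold leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  m <- copula_transform(expr_from_matrix(matrix(rnorm(5 * 20), 5, 20)))
  after_data <- .Random.seed
  invisible(significance_threshold(m, alpha = 0.1, B = 3, seed = 1))
  expect_identical(.Random.seed, after_data)
  expect_false(identical(before, after_data))
})
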