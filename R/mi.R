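#' Parametric Gaussian mutual information between two vectors
#'
#' Computes `-0.5 * log(1 - r^2)` (in nats) where `r` is the sample Pearson
#' correlation. On copula-transformed inputs this is the standard parametric
#' Gaussian MI estimator. `r^2` is clamped at `1 - clamp` so duplicated
#' genes give a large finite value instead of infinity; zero-variance input
#' is treated as `r = 0`, giving MI 0.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param clamp Lower bound on `1 - r^2` (default `1e-12`).
#' @return A single non-negative MI value in nats.
#' @examples
#' x <- seq_len(20)
#' gaussian_mi(x, x)        # clamped maximum, about 13.8
#' gaussian_mi(x, rev(x))   # same: |r| = 1
#' @export
gaussian_mi <- function(x, y, clamp = 1e-12) {
  if (length(x) != length(y)) stop("x and y must have equal length.", call. = FALSE)
  if (length(x) < 3L) stop("Need at least 3 paired samples.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  r <- stats::cor(x, y)
  -0.5 * log(max(1 - r^2, clamp))
}

#' Gene-by-gene mutual information matrix
#'
#' Applies the parametric Gaussian estimator to every unordered gene pair
#' of a (copula-transformed) expression table. The diagonal is set to zero,
#' ignoring self-interactions; the matrix is symmetric by construction.
#'
#' @param m Expression tibble, typically the output of [copula_transform()].
#' @param clamp Correlation clamp passed to the estimator.
#' @return A symmetric numeric matrix (nats) with gene identifiers as
#'   dimnames and zero diagonal.
#' @export
mi_matrix <- function(m, clamp = 1e-12) {
  m <- validate_expression(m, "m")
  vals <- expr_values(m)
  if (nrow(vals) < 2L) stop("mi_matrix needs at least 2 genes.", call. = FALSE)
  if (ncol(vals) < 3L) stop("mi_matrix needs at least 3 samples.", call. = FALSE)
  r <- suppressWarnings(stats::cor(t(vals)))
  r[!is.finite(r)] <- 0 # zero-variance genes: define r = 0
  mi <- -0.5 * log(pmax(1 - r^2, clamp))
  diag(mi) <- 0
  mi[mi < 0] <- 0 # guard tiny negative rounding
  mi
}

#' Row-wise descending ranks of an MI matrix
#'
#' Ranks each row's off-diagonal entries in descending order: rank 1 is the
#' row's largest MI value. Ties take the minimum (competition) rank, so all
#' maximal ties share rank 1. The diagonal gets the sentinel rank `G`
#' (never rank 1 when `G > 1`). The result is generally not symmetric:
#' the rank of the pair (a, b) within row a can differ from its rank within
#' row b.
#'
#' @param mi Symmetric MI matrix from [mi_matrix()].
#' @return An integer matrix of the same shape and dimnames.
#' @export
rank_rows <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  g <- nrow(mi)
  rk <- matrix(g, g, g, dimnames = dimnames(mi))
  for (i in seq_len(g)) {
    off <- setdiff(seq_len(g), i)
    rk[i, off] <- rank(-mi[i, off], ties.method = "min")
  }
  storage.mode(rk) <- "integer"
  rk
}

#' Permutation-null significance threshold for MI values
#'
#' Builds a null distribution of MI under gene independence by permuting
#' each gene's sample order independently and estimating MI on a subset of
#' gene pairs (all pairs when there are at most 100 genes, otherwise
#' `n_pairs` random pairs per round), then returns the empirical
#' `1 - alpha` quantile of the pooled null values. The result is the single
#' global MI cut-off below which an interaction is considered
#' non-significant in the conservative causal core step. Deterministic
#' given the seed.
#'
#' @param m Expression tibble (copula-transformed).
#' @param alpha Significance level in (0, 1).
#' @param B Number of permutation rounds (>= 1).
#' @param n_pairs Pairs sampled per round when the gene set is large.
#' @param seed Integer seed for the permutation generator.
#' @return A single MI threshold in nats.
#' @export
significance_threshold <- function(m, alpha = 0.01, B = 30L, n_pairs = 10000L, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1).", call. = FALSE)
  }
  if (B < 1L) stop("B must be >= 1.", call. = FALSE)
  m <- validate_expression(m, "m")
  vals <- expr_values(m)
  g <- nrow(vals)
  n <- ncol(vals)
  if (g < 2L || n < 3L) stop("Need >= 2 genes and >= 3 samples.", call. = FALSE)

  all_pairs <- g <= 100L
  rng <- local_rng(seed)
  null_mi <- vector("list", B)
  for (b in seq_len(B)) {
    perm <- vals
    for (i in seq_len(g)) perm[i, ] <- perm[i, rng$sample_int(n)]
    if (all_pairs) {
      r <- suppressWarnings(stats::cor(t(perm)))
      r[!is.finite(r)] <- 0
      mi <- -0.5 * log(pmax(1 - r^2, 1e-12))
      null_mi[[b]] <- mi[upper.tri(mi)]
    } else {
      k <- min(n_pairs, g * (g - 1L) / 2)
      ia <- rng$sample_int(g, k, replace = TRUE)
      ib <- rng$sample_int(g, k, replace = TRUE)
      keep <- ia != ib
      ia <- ia[keep]; ib <- ib[keep]
      r <- vapply(seq_along(ia), function(j) {
        stats::cor(perm[ia[j], ], perm[ib[j], ])
      }, numeric(1L))
      r[!is.finite(r)] <- 0
      null_mi[[b]] <- -0.5 * log(pmax(1 - r^2, 1e-12))
    }
  }
  stats::quantile(unlist(null_mi), probs = 1 - alpha, names = FALSE, type = 7)
}

# Seeded RNG scoped to a closure so package calls never disturb the
# caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(f) {
    force(f)
    function(...) {
      prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(prev)) {
          if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
          }
        } else {
          assign(".Random.seed", prev, globalenv())
        }
      })
      f(...)
    }
  }
  list(
    sample_int = with_state(function(n, k = n, replace = FALSE) sample.int(n, k, replace = replace)),
    rnorm = with_state(stats::rnorm),
    runif = with_state(stats::runif)
  )
}
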