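#' Validate an expression tibble
#'
#' An expression table has one row per gene: the first column holds unique,
#' non-empty gene identifiers and every remaining column is one sample of
#' finite numeric expression values. This is the in-memory mirror of the
#' tab-separated input format read by [read_expression()].
#'
#' @param x A data frame to validate.
#' @param arg Name used in error messages.
#' @return `x` as a tibble, invisibly validated.
#' @keywords internal
validate_expression <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    stop(sprintf("`%s` must be a data frame (gene column + sample columns).", arg), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) {
    stop(sprintf("`%s` must have a gene column and at least one sample column.", arg), call. = FALSE)
  }
  genes <- as.character(x[[1L]])
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop(sprintf("`%s` has missing or empty gene identifiers.", arg), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop(sprintf(
      "`%s` has duplicated gene identifiers: %s",
      arg, paste(utils::head(dup, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  vals <- x[-1L]
  bad <- !vapply(vals, is.numeric, logical(1L))
  if (any(bad)) {
    stop(sprintf(
      "`%s` has non-numeric sample columns: %s",
      arg, paste(names(vals)[bad], collapse = ", ")
    ), call. = FALSE)
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "`%s` has a missing/non-finite value at gene '%s', sample '%s'.",
      arg, genes[idx[1L]], colnames(m)[idx[2L]]
    ), call. = FALSE)
  }
  x[[1L]] <- genes
  x
}

# gene-id column + numeric matrix views used by the numeric core
expr_genes <- function(x) as.character(x[[1L]])

expr_values <- function(x) {
  m <- as.matrix(x[-1L])
  rownames(m) <- expr_genes(x)
  m
}

expr_tibble <- function(values, gene_col = "gene") {
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!gene_col := rownames(values)), out)
  out
}

#' Align two expression conditions on a shared gene set
#'
#' Restricts the test and control expression tables to their common genes
#' (in a shared, stable row order) so the two mutual-information matrices
#' are directly comparable. With `keep_all = TRUE` both tables are returned
#' unchanged and the non-shared genes are only reported, so they can be
#' highlighted downstream instead of dropped.
#'
#' @param test,control Expression tibbles (gene column first, then samples).
#' @param keep_all If `TRUE`, do not subset; only report the gene overlap.
#' @return A list with elements `test`, `control` (expression tibbles) and
#'   `report`, a one-row tibble with counts `shared`, `test_only`,
#'   `control_only` and list-columns `test_only_genes`, `control_only_genes`.
#' @examples
#' t <- tibble::tibble(gene = c("A", "B", "C"), s1 = 1:3, s2 = 4:6)
#' c <- tibble::tibble(gene = c("B", "C", "D"), s1 = 1:3, s2 = 4:6)
#' align_conditions(t, c)$report
#' @export
align_conditions <- function(test, control, keep_all = FALSE) {
  test <- validate_expression(test, "test")
  control <- validate_expression(control, "control")
  tg <- expr_genes(test)
  cg <- expr_genes(control)
  shared <- intersect(tg, cg)
  if (length(shared) == 0L) {
    stop("No shared gene identifiers: the two conditions are not comparable.", call. = FALSE)
  }
  report <- tibble::tibble(
    shared = length(shared),
    test_only = length(setdiff(tg, cg)),
    control_only = length(setdiff(cg, tg)),
    test_only_genes = list(setdiff(tg, cg)),
    control_only_genes = list(setdiff(cg, tg))
  )
  if (!keep_all) {
    test <- test[match(shared, tg), , drop = FALSE]
    control <- control[match(shared, cg), , drop = FALSE]
  }
  list(test = test, control = control, report = report)
}

#' Per-gene copula transformation
#'
#' Replaces each gene's expression values by their empirical-CDF positions
#' `rank / (n + 1)` (average ranks for ties), mapping every row into the
#' open interval (0, 1). The transform is invariant to any strictly
#' increasing per-gene change of scale, which is what makes the downstream
#' parametric Gaussian MI estimator distribution-free over monotone
#' transformations of the raw intensities. Constant genes map to all-0.5
#' rows and carry zero MI downstream.
#'
#' @param m Expression tibble.
#' @return Expression tibble of the same shape with transformed values.
#' @examples
#' m <- tibble::tibble(gene = "g1", s1 = 5, s2 = 1, s3 = 3)
#' copula_transform(m) # 0.75, 0.25, 0.5
#' @export
copula_transform <- function(m) {
  m <- validate_expression(m, "m")
  vals <- expr_values(m)
  if (ncol(vals) < 2L) {
    stop("copula_transform needs at least 2 samples per gene.", call. = FALSE)
  }
  n <- ncol(vals)
  tr <- t(apply(vals, 1L, function(row) rank(row, ties.method = "average"))) / (n + 1)
  dimnames(tr) <- dimnames(vals)
  out <- m
  out[-1L] <- tibble::as_tibble(tr)
  out
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample labels, a first column of gene
#' identifiers, and decimal expression values in the remaining cells.
#' Duplicate gene identifiers, missing values and non-numeric cells are
#' errors.
#'
#' @param path Path to a TSV file.
#' @return An expression tibble (first column `gene`).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  x <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, na = character())
  names(x)[1L] <- "gene"
  validate_expression(x, path)
}

#' Write an expression matrix as tab-separated text
#'
#' @param m Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  m <- validate_expression(m, "m")
  readr::write_tsv(m, path, progress = FALSE)
  invisible(path)
}
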