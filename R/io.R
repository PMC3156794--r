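#' Write a network edge list to disk
#'
#' `tsv` writes the full edge record (`gene_a`, `gene_b`, `mi`, `rank_a`,
#' `rank_b`, `category`) sorted by descending MI then pair, so the file
#' can be re-sorted by weight or gene name in any spreadsheet. `sif`
#' writes Cytoscape simple-interaction lines `gene_a pp gene_b` (weights
#' are dropped by that format). Output is byte-identical for identical
#' input.
#'
#' @param net Network tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  net <- dplyr::arrange(net, dplyr::desc(.data$mi), .data$gene_a, .data$gene_b)
  if (format == "tsv") {
    out <- dplyr::mutate(net, mi = sprintf("%.10g", .data$mi))
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    writeLines(sprintf("%s pp %s", net$gene_a, net$gene_b), path)
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Path to a `tsv` or `sif` network file.
#' @param format File format; guessed from the extension by default.
#' @return A network tibble (SIF input yields `NA` weights/ranks and an
#'   empty category).
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (format == "tsv") {
    readr::read_tsv(path, col_types = readr::cols(
      gene_a = readr::col_character(), gene_b = readr::col_character(),
      mi = readr::col_double(), rank_a = readr::col_integer(),
      rank_b = readr::col_integer(), category = readr::col_character()
    ), progress = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    parts <- strsplit(lines[nzchar(lines)], "[ \t]+")
    tibble::tibble(
      gene_a = vapply(parts, `[`, character(1L), 1L),
      gene_b = vapply(parts, `[`, character(1L), 3L),
      mi = NA_real_, rank_a = NA_integer_, rank_b = NA_integer_,
      category = NA_character_
    )
  }
}

#' Run the pipeline on files and write all outputs to a directory
#'
#' Reads the two expression TSVs, runs [run_dc3net()], and writes the six
#' network edge lists (`tnet`, `cnet`, `test_difnet`, `control_difnet`,
#' `common`, `undecided_test`) plus `manifest.json` recording every
#' parameter, the seed, the MI thresholds and the per-network edge
#' counts, so any reported result can be reconstructed from the manifest
#' alone. Identical inputs and seed give byte-identical outputs.
#'
#' @param test_path,control_path Paths to expression TSV files.
#' @param outdir Output directory (created if needed).
#' @param params A [dc3net_params()] list.
#' @param keep_all Passed to [align_conditions()].
#' @param seed Integer seed.
#' @param format Network output format, `"tsv"` or `"sif"`.
#' @return The `dc3net` object, invisibly.
#' @export
dc3net_run_dir <- function(test_path, control_path, outdir,
                           params = dc3net_params(), keep_all = FALSE,
                           seed = 1L, format = "tsv") {
  test <- read_expression(test_path)
  control <- read_expression(control_path)
  fit <- run_dc3net(test, control, params = params, keep_all = keep_all, seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  nets <- c("tnet", "cnet", "test_difnet", "control_difnet", "common", "undecided_test")
  ext <- if (format == "sif") "sif" else "tsv"
  for (nm in nets) {
    write_network(fit[[nm]], file.path(outdir, sprintf("%s.%s", nm, ext)), format = format)
  }
  manifest <- list(
    test = basename(test_path), control = basename(control_path),
    seed = fit$seed,
    params = unclass(fit$params),
    thresholds = as.list(fit$thresholds),
    genes_shared = length(fit$genes),
    alignment = list(
      shared = fit$report$shared, test_only = fit$report$test_only,
      control_only = fit$report$control_only
    ),
    edges = stats::setNames(lapply(nets, function(nm) nrow(fit[[nm]])), nets)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(fit)
}

#' Write a simulated condition pair to disk
#'
#' Writes the test and control expression TSVs and the ground-truth edge
#' table (with its `condition` column) produced by
#' [simulate_condition_pair()].
#'
#' @param sim List from [simulate_condition_pair()].
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$test, file.path(outdir, "test.tsv"))
  write_expression(sim$control, file.path(outdir, "control.tsv"))
  readr::write_tsv(sim$truth, file.path(outdir, "truth.tsv"), progress = FALSE)
  invisible(outdir)
}
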