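#' Write an expression matrix as TSV
#'
#' Header tokens encode the design as `<treatment>_r<replicate>`, so the
#' file round-trips through [read_expression_matrix()].
#'
#' @param x An [expression_matrix()].
#' @param path Output file.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_mat"))
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Write estimate results to a directory
#'
#' Emits the criterion series as tidy TSV, the per-method selection as
#' JSON (with the resolved parameters and seed for reproducibility), and
#' for gDGC the group assignment TSV plus a Newick tree annotated with the
#' cut height.
#'
#' @param est A `k_estimate` from [estimate_k()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_estimate <- function(est, dir) {
  stopifnot(inherits(est, "k_estimate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- tidy(est)
  if (nrow(series))
    readr::write_tsv(series, file.path(dir, "criterion_series.tsv"),
                     progress = FALSE)
  sel <- list(selection = est$summary, params = est$params)
  g <- est$series$gDGC
  if (!is.null(g)) {
    sel$gdgc <- list(Q_observed = g$Q_observed, Q_critical = g$Q_critical,
                     alpha = g$alpha, reject = g$reject, n_groups = g$k)
    readr::write_tsv(tidy(g), file.path(dir, "gdgc_groups.tsv"),
                     progress = FALSE)
    nwk <- dendrogram_newick(g$tree)
    writeLines(c(nwk, sprintf("# cut height Q_crit = %.10g", g$Q_critical)),
               file.path(dir, "gdgc_tree.nwk"))
  }
  jsonlite::write_json(sel, file.path(dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a simulated dataset to a directory
#'
#' The matrix goes to `<name>.tsv`; ground truth (labels, profiles, gene
#' scales, scenario) to `<name>_truth.json`.
#'
#' @param ds A dataset from [simulate_sgem()].
#' @param dir Output directory. @param name Basename for the files.
#' @export
write_sgem <- function(ds, dir, name = "sgem") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(ds$x, file.path(dir, paste0(name, ".tsv")))
  truth <- list(labels = as.list(ds$labels),
                profiles = unname(apply(ds$profiles, 1L, as.list)),
                gene_scale = as.list(ds$gene_scale),
                scenario = unclass(ds$scenario))
  jsonlite::write_json(truth, file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
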