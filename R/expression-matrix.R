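#' Replicated gene-expression matrix
#'
#' Container for a candidate-gene expression matrix: `G` genes measured on
#' `H = T * N` arrays arranged as `T` treatments with `N` replicates each.
#' Replicated designs are required because the pooled within-gene covariance
#' that drives the Mahalanobis geometry is estimated from replicate scatter.
#'
#' @param values Numeric matrix, genes in rows, arrays in columns. No missing
#'   values are allowed.
#' @param treatment Character or factor of length `ncol(values)`: the
#'   treatment label of each column.
#' @param replicate Integer of length `ncol(values)`: the replicate index of
#'   each column within its treatment.
#' @param gene_ids Optional character vector of gene identifiers; defaults to
#'   the row names of `values` or `gene_1 ... gene_G`.
#'
#' @return An object of class `expr_mat`: the validated matrix with columns
#'   reordered treatment-major, replicate-minor, plus design annotation.
#'
#' @details Every `(treatment, replicate)` pair must occur exactly once and
#'   every treatment must have the same number `N >= 2` of replicates.
#'
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3),
#'                        treatment = c("A", "A", "B", "B"),
#'                        replicate = c(1, 2, 1, 2))
#' x$T_treat
#' @export
expression_matrix <- function(values, treatment, replicate, gene_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop_genecut("need at least 2 genes (rows)", "genecut_dim_error")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_genecut(
      sprintf("missing value at gene row %d, column %d", idx[1L], idx[2L]),
      "genecut_missing_error")
  }
  treatment <- as.character(treatment)
  replicate <- as.integer(replicate)
  if (length(treatment) != ncol(values) || length(replicate) != ncol(values))
    stop_genecut("treatment/replicate annotation must match column count",
                 "genecut_layout_error")
  key <- paste(treatment, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop_genecut(sprintf("duplicated (treatment, replicate) pair: %s",
                         gsub("\r", ", replicate ", d)),
                 "genecut_layout_error")
  }
  tr_levels <- unique(treatment)
  if (length(tr_levels) < 2L)
    stop_genecut("need at least 2 treatments", "genecut_layout_error")
  per <- table(treatment)
  if (length(unique(as.integer(per))) != 1L)
    stop_genecut("unbalanced design: treatments have unequal replicate counts",
                 "genecut_layout_error")
  n_rep <- as.integer(per[[1L]])
  if (n_rep < 2L)
    stop_genecut("insufficient replication: every treatment needs N >= 2",
                 "genecut_replication_error")
  # normalize to treatment-major, replicate-minor order
  ord <- order(match(treatment, tr_levels), replicate)
  values <- values[, ord, drop = FALSE]
  treatment <- treatment[ord]
  replicate <- replicate[ord]
  gene_ids <- gene_ids %||% rownames(values) %||%
    paste0("gene_", seq_len(nrow(values)))
  rownames(values) <- gene_ids
  colnames(values) <- paste0(treatment, "_r", replicate)
  structure(
    list(values = values, treatment = treatment, replicate = replicate,
         gene_ids = as.character(gene_ids),
         G = nrow(values), H = ncol(values),
         T_treat = length(tr_levels), N_rep = n_rep,
         treatment_levels = tr_levels),
    class = "expr_mat")
}

#' Read an expression matrix from delimited text
#'
#' Reads a genes-by-arrays table (TSV or CSV, auto-detected from the
#' extension) whose first column holds gene identifiers. The treatment and
#' replicate of each array column are taken either from header tokens of the
#' form `"<treatment>_r<replicate>"` (e.g. `"ctrl_r2"`) or from a separate
#' design file.
#'
#' @param path Path to the matrix file.
#' @param design Optional path to (or data frame of) a design table with
#'   columns `column`, `treatment`, `replicate` mapping each matrix column
#'   name to its design cell.
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, design = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  gene_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  cn <- colnames(values)
  if (!is.null(design)) {
    des <- if (is.character(design))
      readr::read_delim(design, delim = delim, col_types = readr::cols(),
                        progress = FALSE, show_col_types = FALSE)
    else as.data.frame(design)
    need <- c("column", "treatment", "replicate")
    if (!all(need %in% names(des)))
      stop_genecut("design file needs columns: column, treatment, replicate",
                   "genecut_layout_error")
    m <- match(cn, des$column)
    if (anyNA(m))
      stop_genecut(sprintf("design file misses matrix column '%s'",
                           cn[which(is.na(m))[1L]]), "genecut_layout_error")
    treatment <- des$treatment[m]
    replicate <- des$replicate[m]
  } else {
    ok <- grepl("^.+_r[0-9]+$", cn)
    if (!all(ok))
      stop_genecut(
        sprintf("column '%s' does not match '<treatment>_r<replicate>'; %s",
                cn[!ok][1L], "supply a design file instead"),
        "genecut_layout_error")
    treatment <- sub("_r[0-9]+$", "", cn)
    replicate <- as.integer(sub("^.*_r", "", cn))
  }
  expression_matrix(values, treatment, replicate, gene_ids = gene_ids)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d genes x %d arrays (%d treatments x %d replicates)\n",
    x$G, x$H, x$T_treat, x$N_rep))
  cat("treatments:", paste(x$treatment_levels, collapse = ", "), "\n")
  invisible(x)
}

#' @method as_tibble expr_mat
#' @export
as_tibble.expr_mat <- function(x, ...) {
  out <- tibble::as_tibble(x$values, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(gene = x$gene_ids), out)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)
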