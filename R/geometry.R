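#' Per-gene treatment mean profiles
#'
#' Averages the `N` replicate columns of each treatment, returning the
#' `G x T` matrix of mean profiles that all cluster-number estimators work on.
#'
#' @param x An [expression_matrix()].
#' @return Numeric matrix, genes in rows, treatments in columns.
#' @export
treatment_means <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  idx <- match(x$treatment, x$treatment_levels)
  m <- t(rowsum(t(x$values), idx)) / x$N_rep
  colnames(m) <- x$treatment_levels
  rownames(m) <- x$gene_ids
  m
}

#' Pooled within-gene covariance
#'
#' Estimates the common within-gene covariance `S` across treatments by
#' pooling replicate deviations over all genes:
#' `S = sum_i sum_r (y_ir - ybar_i)(y_ir - ybar_i)' / (G (N - 1))`,
#' where `y_ir` is the length-`T` vector formed by replicate `r` of gene `i`
#' across treatments. Replicate index pairs columns across treatments, so `S`
#' carries between-treatment covariances of paired hybridisations; set
#' `type = "diagonal"` to pool per-treatment variances only (unpaired
#' designs).
#'
#' @param x An [expression_matrix()].
#' @param type `"full"` (default) or `"diagonal"`.
#' @return A list with elements `S` (`T x T` matrix) and `df = G * (N - 1)`.
#' @export
pooled_within_covariance <- function(x, type = c("full", "diagonal")) {
  stopifnot(inherits(x, "expr_mat"))
  type <- match.arg(type)
  if (x$N_rep < 2L)
    stop_genecut("insufficient replication: N >= 2 required",
                 "genecut_replication_error")
  p <- x$T_treat
  # stack the per-gene, per-replicate T-vectors as rows of a (G*N) x T matrix
  tr_idx <- match(x$treatment, x$treatment_levels)
  ord <- order(x$replicate, tr_idx)            # replicate-major blocks
  v <- x$values[, ord, drop = FALSE]
  # stack to rows (gene, replicate) x treatments: row (r-1)*G + i = y_ir
  a <- array(v, dim = c(x$G, p, x$N_rep))
  y <- matrix(aperm(a, c(1L, 3L, 2L)), ncol = p)
  gene_of_row <- rep(seq_len(x$G), times = x$N_rep)
  means <- rowsum(y, gene_of_row) / x$N_rep
  dev <- y - means[gene_of_row, , drop = FALSE]
  df <- x$G * (x$N_rep - 1L)
  S <- crossprod(dev) / df
  if (type == "diagonal") S <- diag(diag(S), nrow = p)
  dimnames(S) <- list(x$treatment_levels, x$treatment_levels)
  list(S = S, df = df)
}

# Symmetric inverse square root of S, with a ridge fallback for
# near-singular estimates. Returns the p x p matrix S^(-1/2).
inv_sqrt_covariance <- function(S, ridge = 1e-8) {
  p <- nrow(S)
  e <- eigen(S, symmetric = TRUE)
  tol <- 1e-12 * max(abs(e$values), 1e-300)
  if (any(e$values <= tol)) {
    if (is.null(ridge))
      stop_genecut("pooled covariance is singular", "genecut_singular_error")
    rlang::warn(sprintf(
      "pooled covariance near-singular; adding ridge %g * mean(diag)", ridge))
    S <- S + ridge * mean(diag(S)) * diag(p)
    e <- eigen(S, symmetric = TRUE)
    if (any(e$values <= tol))
      stop_genecut("pooled covariance singular even after ridge",
                   "genecut_singular_error")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Whiten mean profiles by the pooled covariance
#'
#' Applies the symmetric inverse square root of `S` to every mean-profile
#' row, so that Euclidean distances between whitened profiles equal the
#' Mahalanobis distances used by the clustering. All sum-of-squares-based
#' criteria (CH, Hartigan, CCC, gap) are evaluated in these coordinates.
#'
#' @param means `G x T` matrix of mean profiles (see [treatment_means()]).
#' @param S Pooled covariance matrix or the list returned by
#'   [pooled_within_covariance()].
#' @param ridge Relative ridge added when `S` is numerically singular;
#'   `NULL` disables the fallback and errors instead.
#' @return Matrix of the same shape as `means`.
#' @export
whiten_means <- function(means, S, ridge = 1e-8) {
  if (is.list(S)) S <- S$S
  means %*% inv_sqrt_covariance(S, ridge)
}

#' Mahalanobis distance matrix between mean profiles
#'
#' `D[i, j] = sqrt((ybar_i - ybar_j)' S^{-1} (ybar_i - ybar_j))`, the
#' dissimilarity between gene mean vectors standardised by the pooled
#' within-gene covariance.
#'
#' @inheritParams whiten_means
#' @return Symmetric `G x G` matrix with zero diagonal.
#' @export
mahalanobis_distance_matrix <- function(means, S, ridge = 1e-8) {
  if (is.list(S)) S <- S$S
  w <- means %*% inv_sqrt_covariance(S, ridge)
  d <- as.matrix(stats::dist(w))
  dimnames(d) <- list(rownames(means), rownames(means))
  d
}

#' Write a distance matrix as square TSV
#'
#' @param d Symmetric distance matrix with row/column names.
#' @param path Output file.
#' @export
write_distance_matrix <- function(d, path) {
  out <- data.frame(gene = rownames(d), d, check.names = FALSE)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
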