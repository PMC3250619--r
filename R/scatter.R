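#' Within- and between-cluster scatter of a partition
#'
#' For data `X` (`n x p`) partitioned into `k` clusters, computes the cluster
#' mean matrix `C`, the pooled within-cluster scatter
#' `W = (X - ZC)'(X - ZC)`, the between-cluster scatter
#' `B = sum_r n_r (c_r - xbar)(c_r - xbar)'` (cluster means centred at the
#' grand mean so that `W + B` equals the total centred scatter), and their
#' traces `W(k)`, `B(k)`.
#'
#' @param x Numeric matrix of instances by features (whitened mean profiles
#'   in this package's pipeline).
#' @param labels Integer cluster labels `1..k`, one per row of `x`; every
#'   cluster must be non-empty.
#' @return List with `C`, `W_matrix`, `B_matrix`, `W_k`, `B_k`, `total`,
#'   `k`, `n`.
#' @export
scatter_decomposition <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  n <- nrow(x)
  if (length(labels) != n)
    stop_genecut("one label per row required", "genecut_partition_error")
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0L))
    stop_genecut("empty cluster in partition", "genecut_partition_error")
  grand <- colMeans(x)
  C <- rowsum(x, labels) / sizes
  dev_w <- x - C[labels, , drop = FALSE]
  W <- crossprod(dev_w)
  dev_b <- sqrt(sizes) * (C - rep(grand, each = k))
  B <- crossprod(dev_b)
  xc <- x - rep(grand, each = n)
  list(C = C, W_matrix = W, B_matrix = B,
       W_k = sum(dev_w^2), B_k = sum(dev_b^2), total = sum(xc^2),
       k = k, n = n)
}

# Between-cluster trace B(k) for each column of a label matrix, plus total.
# Used on the hot path (criterion series, reference draws) where only the
# traces are needed.
trace_path <- function(x, label_matrix) {
  n <- nrow(x)
  grand <- colMeans(x)
  xc <- x - rep(grand, each = n)
  total <- sum(xc^2)
  B_k <- vapply(seq_len(ncol(label_matrix)), function(j) {
    lab <- label_matrix[, j]
    sizes <- tabulate(lab)
    C <- rowsum(xc, lab) / sizes
    sum(sizes * C^2)
  }, numeric(1))
  list(total = total, B_k = B_k, W_k = total - B_k)
}

# Shared per-dataset machinery: whitened coordinates, Mahalanobis distances,
# the dendrogram, its cut path up to kmax, and the W(k)/B(k) traces.
cluster_path <- function(x, linkage = "average", kmax = NULL, ridge = 1e-8) {
  stopifnot(inherits(x, "expr_mat"))
  m <- treatment_means(x)
  S <- pooled_within_covariance(x)
  xw <- whiten_means(m, S, ridge = ridge)
  d <- as.matrix(stats::dist(xw))
  dimnames(d) <- list(x$gene_ids, x$gene_ids)
  tree <- agglomerate(d, linkage)
  n <- nrow(xw)
  kmax <- min(kmax %||% min(20L, n - 1L), n - 1L)
  ks <- seq_len(kmax + 1L)                 # Hartigan needs W(kmax + 1)
  cuts <- stats::cutree(tree, k = ks)
  tp <- trace_path(xw, cuts)
  list(x = x, means = m, S = S, xw = xw, d = d, tree = tree,
       kmax = kmax, ks = ks, cuts = cuts,
       W_k = tp$W_k, B_k = tp$B_k, total = tp$total)
}
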