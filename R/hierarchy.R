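#' Agglomerative clustering of a distance matrix
#'
#' Builds the hierarchy used by every estimator in the package. Average
#' linkage merges, at each step, the pair of clusters with the smallest
#' unweighted mean of cross-pair leaf distances (UPGMA); complete linkage
#' uses the largest cross-pair distance. Merge heights `q_1 <= ... <= q_(n-1)`
#' are non-decreasing for both linkages; the final height is the root-node
#' distance `Q`, the test statistic of [gdgc_test()].
#'
#' @param d Symmetric distance matrix (or `dist` object), `n >= 2` leaves.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An [stats::hclust] tree with an added `linkage` attribute.
#' @export
agglomerate <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) < 2L)
      stop_genecut("need at least 2 leaves to agglomerate",
                   "genecut_dim_error")
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2L)
    stop_genecut("need at least 2 leaves to agglomerate", "genecut_dim_error")
  h <- stats::hclust(d, method = linkage)
  attr(h, "linkage") <- linkage
  h
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges of the tree, yielding the partition the
#' criteria evaluate at each candidate `k`.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels in `1..k`, named by leaf labels.
#' @export
cut_tree_at_k <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n)
    stop_genecut(sprintf("k must be in [1, %d]", n), "genecut_argument_error")
  stats::cutree(tree, k = k)
}

#' Root-node distance of a dendrogram
#'
#' The merge height at which the final two clusters join; under the null
#' hypothesis of equal mean profiles it is a draw from the reference
#' distribution simulated by [simulate_null_q()].
#'
#' @param tree An [stats::hclust] tree.
#' @return The height of the last merge.
#' @export
root_distance <- function(tree) {
  tree$height[length(tree$height)]
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights via [ape::as.phylo].
#'
#' @param tree An [stats::hclust] tree.
#' @param path Optional file to write to; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Merge table of a dendrogram
#'
#' @param tree An [stats::hclust] tree.
#' @return Tibble with one row per merge: step, members of each side, height.
#' @export
merge_table <- function(tree) {
  n <- length(tree$order)
  labs <- tree$labels %||% as.character(seq_len(n))
  members <- vector("list", n - 1L)
  side <- function(code, step_members) {
    if (code < 0) labs[-code] else step_members[[code]]
  }
  a_str <- b_str <- character(n - 1L)
  for (s in seq_len(n - 1L)) {
    a <- side(tree$merge[s, 1L], members)
    b <- side(tree$merge[s, 2L], members)
    members[[s]] <- c(a, b)
    a_str[s] <- paste(a, collapse = ",")
    b_str[s] <- paste(b, collapse = ",")
  }
  tibble::tibble(step = seq_len(n - 1L), members_a = a_str, members_b = b_str,
                 height = tree$height)
}
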