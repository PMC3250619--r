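#' Monte-Carlo null distribution of the root-node distance
#'
#' Under the null hypothesis that all `n` genes share one population mean
#' profile, each replicate draws `n * N` independent standard-normal
#' `p`-vectors, forms gene means and the pooled within-gene covariance with
#' the same conventions as [pooled_within_covariance()], computes
#' Mahalanobis distances, agglomerates, and records the root-node distance
#' `Q`. Mahalanobis standardisation makes the resulting distribution
#' invariant to the true within-gene covariance under multivariate
#' normality, so identity-covariance draws suffice; re-estimating the
#' covariance in every replicate keeps its sampling noise in the null.
#'
#' @param n Genes. @param p Treatments. @param N Replicates per treatment.
#' @param linkage `"average"` or `"complete"`.
#' @param B_null Number of null replicates (values below 100 give unstable
#'   tail quantiles and trigger a warning).
#' @param seed Optional integer seed (fixed seed gives identical samples).
#' @return A `null_q` object holding the sorted samples and the design.
#' @export
simulate_null_q <- function(n, p, N, linkage = c("average", "complete"),
                            B_null = 1000L, seed = NULL) {
  linkage <- match.arg(linkage)
  if (n < 2L || p < 1L || N < 2L)
    stop_genecut("need n >= 2, p >= 1, N >= 2", "genecut_argument_error")
  if (B_null < 100L)
    rlang::warn("B_null < 100: tail quantiles of Q will be unstable")
  gene_of_row <- rep(seq_len(n), each = N)
  df <- n * (N - 1L)
  run <- function() {
    y <- matrix(stats::rnorm(n * N * p), n * N, p)
    means <- rowsum(y, gene_of_row) / N
    dev <- y - means[gene_of_row, , drop = FALSE]
    S <- crossprod(dev) / df
    xw <- means %*% inv_sqrt_covariance(S)
    tree <- stats::hclust(stats::dist(xw), method = linkage)
    tree$height[n - 1L]
  }
  q <- if (is.null(seed)) replicate(B_null, run())
       else with_seed(seed, replicate(B_null, run()))
  structure(
    list(samples = sort(q), B_null = as.integer(B_null), n = n, p = p, N = N,
         linkage = linkage, seed = seed),
    class = "null_q")
}

#' @export
print.null_q <- function(x, ...) {
  cat(sprintf(
    "<null_q> %d root distances under H0 (n = %d, p = %d, N = %d, %s)\n",
    x$B_null, x$n, x$p, x$N, x$linkage))
  print(stats::quantile(x$samples, c(0.5, 0.9, 0.95, 0.99)))
  invisible(x)
}

#' Critical value of the root-distance null distribution
#'
#' The empirical `(1 - alpha)`-quantile of the simulated `Q` samples
#' (type-7 interpolation between order statistics).
#'
#' @param null A `null_q` object from [simulate_null_q()].
#' @param alpha Significance level in (0, 1).
#' @export
critical_value <- function(null, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_genecut("alpha must lie in (0, 1)", "genecut_argument_error")
  samples <- if (inherits(null, "null_q")) null$samples else as.numeric(null)
  unname(stats::quantile(samples, probs = 1 - alpha, type = 7))
}

#' Cache for null distributions of Q
#'
#' Simulating the null of the root distance is the expensive part of the
#' gDGC test but depends only on `(n, p, N, linkage, B_null, seed)`; a cache
#' environment lets repeated tests on same-shaped data reuse one simulation.
#'
#' @return An empty environment to pass as `null_cache`/`cache`.
#' @export
null_cache <- function() new.env(parent = emptyenv())

get_null_q <- function(n, p, N, linkage, B_null, seed, cache = NULL) {
  if (is.null(cache))
    return(simulate_null_q(n, p, N, linkage, B_null, seed))
  key <- paste(n, p, N, linkage, B_null, seed %||% "none", sep = "|")
  if (is.null(cache[[key]]))
    cache[[key]] <- simulate_null_q(n, p, N, linkage, B_null, seed)
  cache[[key]]
}

# bootstrap null: replicate-level residual vectors resampled with
# replacement within genes, then the same pipeline as the gaussian null
simulate_null_q_bootstrap <- function(x, linkage, B_null = 1000L,
                                      seed = NULL) {
  n <- x$G; p <- x$T_treat; N <- x$N_rep
  tr_idx <- match(x$treatment, x$treatment_levels)
  ord <- order(x$replicate, tr_idx)
  v <- x$values[, ord, drop = FALSE]
  a <- array(v, dim = c(n, p, N))
  y <- matrix(aperm(a, c(1L, 3L, 2L)), ncol = p)
  gene_of_row <- rep(seq_len(n), times = N)
  means0 <- rowsum(y, gene_of_row) / N
  resid <- y - means0[gene_of_row, , drop = FALSE]
  by_gene <- split.data.frame(resid, gene_of_row)
  df <- n * (N - 1L)
  run <- function() {
    rows <- lapply(by_gene, function(e)
      e[sample.int(nrow(e), nrow(e), replace = TRUE), , drop = FALSE])
    yb <- do.call(rbind, rows)
    g <- rep(seq_len(n), each = N)
    means <- rowsum(yb, g) / N
    dev <- yb - means[g, , drop = FALSE]
    S <- crossprod(dev) / df
    xw <- means %*% inv_sqrt_covariance(S)
    tree <- stats::hclust(stats::dist(xw), method = linkage)
    tree$height[n - 1L]
  }
  q <- if (is.null(seed)) replicate(B_null, run())
       else with_seed(seed, replicate(B_null, run()))
  structure(
    list(samples = sort(q), B_null = as.integer(B_null), n = n, p = p, N = N,
         linkage = linkage, seed = seed),
    class = "null_q")
}

# groups = maximal clusters whose internal merges all sit strictly below h
cut_at_height <- function(tree, h) {
  n <- length(tree$order)
  stats::cutree(tree, k = n - sum(tree$height < h))
}

group_letters <- function(labels, order) {
  k <- max(labels)
  first <- match(seq_len(k), labels[order])
  rank <- match(seq_len(k), seq_len(k)[order(first)])
  alphabet <- c(letters, as.vector(outer(letters, letters, paste0)))
  stats::setNames(alphabet[rank][labels], names(labels))
}

gdgc_from_path <- function(cp, alpha = 0.05, B_null = 1000L, seed = NULL,
                           cache = NULL, null = c("gaussian", "bootstrap")) {
  null <- match.arg(null)
  x <- cp$x
  tree <- cp$tree
  Q_obs <- root_distance(tree)
  nq <- if (null == "gaussian")
    get_null_q(x$G, x$T_treat, x$N_rep, attr(tree, "linkage"),
               B_null, seed, cache)
  else simulate_null_q_bootstrap(x, attr(tree, "linkage"), B_null, seed)
  Q_crit <- critical_value(nq, alpha)
  reject <- Q_obs >= Q_crit
  labels <- if (!reject) stats::setNames(rep(1L, x$G), x$gene_ids)
            else cut_at_height(tree, Q_crit)
  structure(
    list(Q_observed = Q_obs, Q_critical = Q_crit, alpha = alpha,
         reject = reject, k = max(labels), labels = labels,
         letters = group_letters(labels, tree$order),
         tree = tree, null = nq, linkage = attr(tree, "linkage")),
    class = "gdgc_result")
}

#' gDGC test: a significance-calibrated dendrogram cut
#'
#' Tests the null hypothesis that all genes share one population mean
#' profile by comparing the observed root-node distance `Q` of the
#' Mahalanobis dendrogram with the `(1 - alpha)`-quantile of its simulated
#' null distribution. When the null is rejected, the dendrogram is cut at
#' the critical height: the groups are the maximal clusters all of whose
#' internal merges sit strictly below `Q_critical`, and each group receives
#' a letter code in dendrogram leaf order (genes with different letters
#' differ significantly in their population profiles at level `alpha`).
#'
#' @param x An [expression_matrix()].
#' @param linkage `"average"` or `"complete"`.
#' @param alpha Significance level.
#' @param B_null Null replicates for the distribution of `Q`.
#' @param seed Optional integer seed for the null simulation.
#' @param cache Optional [null_cache()] environment.
#' @param null `"gaussian"` (default; multivariate-normal null replicates)
#'   or `"bootstrap"` (replicate residuals resampled within genes).
#' @return A `gdgc_result`; `glance()` summarises the test, `tidy()` gives
#'   the per-gene group assignment.
#' @examples
#' x <- simulate_sgem(synthesize_rgem(200, 10, seed = 1),
#'                    scenario(G = 40, k = 2, T_treat = 3, N_rep = 3),
#'                    seed = 2)$x
#' res <- gdgc_test(x, B_null = 200, seed = 3)
#' glance(res)
#' @export
gdgc_test <- function(x, linkage = c("average", "complete"), alpha = 0.05,
                      B_null = 1000L, seed = NULL, cache = NULL,
                      null = c("gaussian", "bootstrap")) {
  linkage <- match.arg(linkage)
  cp <- cluster_path(x, linkage = linkage, kmax = 2L)
  gdgc_from_path(cp, alpha = alpha, B_null = B_null, seed = seed,
                 cache = cache, null = null)
}

#' @export
print.gdgc_result <- function(x, ...) {
  cat(sprintf("<gdgc_result> Q = %.4f, Q_crit(alpha = %g) = %.4f -> %s\n",
              x$Q_observed, x$alpha, x$Q_critical,
              if (x$reject) sprintf("%d groups", x$k) else "1 group (H0 kept)"))
  invisible(x)
}

#' Table of critical values over design grids
#'
#' Precomputes `Q_(1-alpha)` for every combination of genes, treatments,
#' replicates and significance level, the way one would tabulate percentile
#' points for repeated use.
#'
#' @param n,p,N Vectors of design sizes.
#' @param alpha Vector of significance levels.
#' @param linkage `"average"` or `"complete"`.
#' @param B_null Null replicates per combination.
#' @param seed Integer master seed; each combination derives its own seed.
#' @return Tibble with columns `n, p, N, alpha, linkage, B_null, Q_crit`.
#' @export
null_table <- function(n, p, N, alpha = 0.05,
                       linkage = c("average", "complete"),
                       B_null = 1000L, seed = 1L) {
  linkage <- match.arg(linkage)
  grid <- expand.grid(n = n, p = p, N = N, KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::pmap(grid, function(n, p, N) {
    nq <- simulate_null_q(n, p, N, linkage, B_null,
                          seed = derive_seed(seed, "null_table", n, p, N))
    tibble::tibble(n = n, p = p, N = N, alpha = alpha, linkage = linkage,
                   B_null = B_null,
                   Q_crit = vapply(alpha, function(a) critical_value(nq, a),
                                   numeric(1)))
  })
  dplyr::bind_rows(rows)
}
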