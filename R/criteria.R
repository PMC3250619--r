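#' @title Cluster-number criteria along a dendrogram cut path
#' @name criteria
#' @description
#' All criteria in this package score the partitions obtained by cutting one
#' hierarchical tree at `k = 1, 2, ..., Kmax` clusters. Sum-of-squares based
#' criteria (CH, Hartigan, CCC/CCCm, gap) are evaluated on whitened mean
#' profiles, where Euclidean geometry reproduces the Mahalanobis distances
#' the tree was built from; the silhouette works on the distance matrix
#' directly. Each criterion applies its published selection rule to produce
#' `k_hat`.
NULL

new_criterion_series <- function(method, k_values, scores, k_hat,
                                 aux = NULL, flag = NA_character_) {
  structure(
    list(method = method, k_values = k_values, scores = scores,
         k_hat = k_hat, aux = aux, flag = flag),
    class = "criterion_series")
}

#' @export
print.criterion_series <- function(x, ...) {
  cat(sprintf("<criterion_series> %s: k_hat = %d%s\n", x$method, x$k_hat,
              if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Calinski-Harabasz criterion
#'
#' `CH(k) = (B(k) / (k - 1)) / (W(k) / (n - k))`, maximised over
#' `k = 2..Kmax`. A cut with zero within-cluster scatter scores `+Inf` and
#' is flagged.
#'
#' @param W_k,B_k Within- and between-cluster trace paths, indexed by
#'   `k = 1, 2, ...` (element `k` is the value at `k` clusters).
#' @param n Number of instances.
#' @param kmax Largest `k` evaluated.
#' @return A `criterion_series` with `k_hat = argmax CH(k)`.
#' @export
criterion_ch <- function(W_k, B_k, n, kmax) {
  total <- W_k[1L] + B_k[1L]
  if (total <= 0)
    stop_genecut("all instances identical: CH undefined",
                 "genecut_degenerate_error")
  ks <- 2:kmax
  ch <- (B_k[ks] / (ks - 1)) / (W_k[ks] / (n - ks))
  flag <- if (any(!is.finite(ch))) "infinite_score" else NA_character_
  k_hat <- ks[which.max(ch)]
  new_criterion_series("CH", ks, ch, k_hat, flag = flag)
}

#' Hartigan rule
#'
#' `H(k) = ((W(k) / W(k+1)) - 1) (n - k - 1)`; the estimate is the smallest
#' `k >= 1` with `H(k) < 10`. If no `k` satisfies the rule up to `Kmax` the
#' series is flagged `unresolved` and `k_hat = Kmax`.
#'
#' @inheritParams criterion_ch
#' @param W_k Within-cluster trace path covering `k = 1..Kmax + 1`.
#' @export
criterion_hartigan <- function(W_k, n, kmax) {
  ks <- seq_len(kmax)
  h <- (W_k[ks] / W_k[ks + 1L] - 1) * (n - ks - 1)
  hit <- which(h < 10)
  if (length(hit)) {
    new_criterion_series("H", ks, h, ks[hit[1L]],
                         flag = if (any(!is.finite(h))) "infinite_score"
                                else NA_character_)
  } else {
    new_criterion_series("H", ks, h, kmax, flag = "unresolved")
  }
}

# Reference draws for CCC/CCCm/gap: B_ref datasets of n points uniform on
# the axis-aligned bounding hypercube of x ("hypercube") or on the box
# aligned with its principal components ("pca_box"), each clustered with the
# same linkage and cut at k = 1..kmax. Returns per-draw log W*(k) and R2*(k).
reference_null_paths <- function(x, linkage, kmax, null = c("hypercube", "pca_box"),
                                 B_ref = 100L, seed = NULL) {
  null <- match.arg(null)
  n <- nrow(x); p <- ncol(x)
  ctr <- colMeans(x)
  xc <- x - rep(ctr, each = n)
  if (sum(xc^2) <= 0)
    stop_genecut("zero-volume reference box: data are constant",
                 "genecut_degenerate_error")
  if (null == "pca_box") {
    V <- svd(xc, nu = 0)$v
    sc <- xc %*% V
  } else {
    V <- NULL
    sc <- xc
  }
  lo <- apply(sc, 2L, min); hi <- apply(sc, 2L, max)
  run <- function() {
    z <- matrix(stats::runif(n * p, rep(lo, each = n), rep(hi, each = n)),
                n, p)
    if (!is.null(V)) z <- z %*% t(V)
    tree <- stats::hclust(stats::dist(z), method = linkage)
    tp <- trace_path(z, stats::cutree(tree, k = seq_len(kmax)))
    c(log(tp$W_k), tp$B_k / tp$total)
  }
  draws <- if (is.null(seed)) replicate(B_ref, run())
           else with_seed(seed, replicate(B_ref, run()))
  list(logW = t(draws[seq_len(kmax), , drop = FALSE]),
       R2 = t(draws[kmax + seq_len(kmax), , drop = FALSE]))
}

#' Monte-Carlo expected explained variance under a uniform null
#'
#' Estimates `E(R^2)` at each `k` by clustering reference datasets drawn
#' uniformly on the bounding hypercube of the data (`null = "hypercube"`,
#' classical CCC) or on the box aligned with its principal components
#' (`null = "pca_box"`, the CCCm variant).
#'
#' @param x Data matrix (whitened mean profiles).
#' @param linkage Linkage used for the reference clusterings.
#' @param kmax Largest `k` evaluated.
#' @param null Reference null: `"hypercube"` or `"pca_box"`.
#' @param B_ref Number of reference datasets.
#' @param seed Optional integer seed for the reference draws.
#' @return Numeric vector `E(R^2)(k)` for `k = 1..kmax`.
#' @export
expected_r2_reference <- function(x, linkage = "average", kmax,
                                  null = c("hypercube", "pca_box"),
                                  B_ref = 100L, seed = NULL) {
  ref <- reference_null_paths(x, linkage, kmax, null, B_ref, seed)
  colMeans(ref$R2)
}

#' Cubic clustering criterion
#'
#' `CCC(k) = ln((1 - E(R^2)) / (1 - R^2)) * sqrt(n p* / 2) /
#' (0.001 + E(R^2))^1.2` with `p* = min(k - 1, p)`, maximised over
#' `k = 2..Kmax`. A maximum below 2 is taken as no evidence of clustering
#' and `k_hat = 1` is returned (flag `no_evidence`).
#'
#' @param R2 Observed `B(k)/total` path indexed by `k`.
#' @param E_R2 Expected `R^2` path under the uniform null (same indexing).
#' @param n,p Instances and features.
#' @param kmax Largest `k` evaluated.
#' @param variant Label for the series: `"CCC"` or `"CCCm"`.
#' @export
criterion_ccc <- function(R2, E_R2, n, p, kmax, variant = c("CCC", "CCCm")) {
  variant <- match.arg(variant)
  ks <- 2:kmax
  pstar <- pmin(ks - 1, p)
  ccc <- log((1 - E_R2[ks]) / (1 - R2[ks])) * sqrt(n * pstar / 2) /
    (0.001 + E_R2[ks])^1.2
  aux <- tibble::tibble(k = ks, R2 = R2[ks], E_R2 = E_R2[ks])
  if (all(is.na(ccc)))
    stop_genecut("CCC undefined on every k", "genecut_degenerate_error")
  best <- max(ccc, na.rm = TRUE)
  if (is.na(best) || best < 2) {
    new_criterion_series(variant, ks, ccc, 1L, aux = aux, flag = "no_evidence")
  } else {
    new_criterion_series(variant, ks, ccc, ks[which.max(ccc)], aux = aux,
                         flag = if (any(is.infinite(ccc))) "infinite_score"
                                else NA_character_)
  }
}

# silhouette widths for one partition on a distance matrix
silhouette_widths <- function(d, labels) {
  n <- nrow(d)
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  sums <- t(rowsum(t(d), labels))            # n x k: sum of d(i, cluster c)
  own <- labels
  a <- sums[cbind(seq_len(n), own)] / pmax(sizes[own] - 1L, 1L)
  mean_other <- sums / rep(sizes, each = n)
  mean_other[cbind(seq_len(n), own)] <- Inf
  b <- apply(mean_other, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1L] <- 0                   # singleton convention
  s[!is.finite(s)] <- 0
  s
}

#' Average-silhouette criterion
#'
#' For each instance, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)`
#' the mean distance to its own cluster and `b(i)` the mean distance to the
#' nearest other cluster; singletons score 0. `k_hat` maximises the average
#' silhouette over `k = 2..Kmax`, computed on the Mahalanobis distance
#' matrix.
#'
#' @param d Symmetric distance matrix.
#' @param cuts `n x Kmax` matrix of cut labels (column `k` = partition into
#'   `k` clusters), e.g. from [stats::cutree].
#' @param kmax Largest `k` evaluated.
#' @export
criterion_silhouette <- function(d, cuts, kmax) {
  d <- as.matrix(d)
  ks <- 2:kmax
  avg <- vapply(ks, function(k) mean(silhouette_widths(d, cuts[, k])),
                numeric(1))
  new_criterion_series("Silh", ks, avg, ks[which.max(avg)])
}

#' Gap statistic
#'
#' `gap(k) = E[log W(k)] - log W(k)`, the expectation estimated from `B_ref`
#' reference datasets drawn uniformly on the principal-component-aligned box
#' of the data and clustered with the same linkage. The estimate is the
#' smallest `k` with `gap(k) >= gap(k + 1) - s(k + 1)`, where `s(k)` is the
#' reference standard deviation of `log W*(k)` inflated by
#' `sqrt(1 + 1/B_ref)`. If the rule never fires `k_hat = Kmax` (flag
#' `unresolved`).
#'
#' @param x Data matrix (whitened mean profiles).
#' @param W_k Observed within-cluster trace path for `k = 1..Kmax`.
#' @param linkage Linkage for the reference clusterings.
#' @param kmax Largest `k` evaluated.
#' @param B_ref Number of reference datasets.
#' @param seed Optional integer seed.
#' @export
criterion_gap <- function(x, W_k, linkage = "average", kmax,
                          B_ref = 50L, seed = NULL) {
  ref <- reference_null_paths(x, linkage, kmax, "pca_box", B_ref, seed)
  ks <- seq_len(kmax)
  gap <- colMeans(ref$logW) - log(W_k[ks])
  s <- apply(ref$logW, 2L, stats::sd) * sqrt(1 + 1 / B_ref)
  k_hat <- gap_select(gap, s)
  aux <- tibble::tibble(k = ks, gap = gap, s = s,
                        E_logW = colMeans(ref$logW))
  if (is.na(k_hat))
    new_criterion_series("Gap", ks, gap, kmax, aux = aux, flag = "unresolved")
  else
    new_criterion_series("Gap", ks, gap, k_hat, aux = aux)
}

# one-standard-error selection rule: smallest k with
# gap(k) >= gap(k+1) - s(k+1); NA when never satisfied
gap_select <- function(gap, s) {
  kmax <- length(gap)
  ok <- which(gap[-kmax] >= gap[-1L] - s[-1L])
  if (length(ok)) ok[1L] else NA_integer_
}

#' Estimate the number of clusters in an expression matrix
#'
#' Single entry point running the full pipeline: treatment means, pooled
#' within-gene covariance, whitening, Mahalanobis distances, hierarchical
#' tree, then every requested criterion with its selection rule. `"gDGC"`
#' delegates to [gdgc_test()] with the same tree and a simulated null for
#' the root-node distance.
#'
#' @param x An [expression_matrix()].
#' @param methods Character vector from
#'   `c("gDGC", "CH", "H", "CCC", "CCCm", "Silh", "Gap")` (default: all).
#' @param linkage `"average"` or `"complete"`.
#' @param alpha Significance level for gDGC.
#' @param B_null Null replicates for the gDGC root-distance distribution.
#' @param B_ref_gap,B_ref_ccc Reference draws for gap and CCC/CCCm.
#' @param kmax Largest `k` evaluated; default `min(20, G - 1)`.
#' @param seed Integer master seed; per-criterion seeds are derived from it.
#' @param null_seed Seed for the gDGC null simulation; defaults to a value
#'   derived from `seed`. Pass a seed derived from the design only to share
#'   cached null distributions across datasets of the same shape.
#' @param null_cache Optional environment caching gDGC null distributions
#'   across calls (see [null_cache()]).
#' @return A `k_estimate` object; `glance()` gives one row per method with
#'   `k_hat`, `tidy()` the long table of criterion scores.
#' @examples
#' x <- simulate_sgem(synthesize_rgem(500, 10, seed = 1),
#'                    scenario(G = 60, k = 2, T_treat = 3, N_rep = 3),
#'                    seed = 2)$x
#' est <- estimate_k(x, methods = c("CH", "Silh"), seed = 3)
#' glance(est)
#' @export
estimate_k <- function(x, methods = c("gDGC", "CH", "H", "CCC", "CCCm",
                                      "Silh", "Gap"),
                       linkage = c("average", "complete"), alpha = 0.05,
                       B_null = 1000L, B_ref_gap = 50L, B_ref_ccc = 100L,
                       kmax = NULL, seed = 1L, null_seed = NULL,
                       null_cache = NULL) {
  linkage <- match.arg(linkage)
  methods <- match.arg(methods, several.ok = TRUE)
  cp <- cluster_path(x, linkage = linkage, kmax = kmax)
  n <- cp$x$G; p <- cp$x$T_treat; km <- cp$kmax
  series <- list()
  for (m in methods) {
    series[[m]] <- switch(
      m,
      CH = criterion_ch(cp$W_k, cp$B_k, n, km),
      H = criterion_hartigan(cp$W_k, n, km),
      Silh = criterion_silhouette(cp$d, cp$cuts, km),
      Gap = criterion_gap(cp$xw, cp$W_k, linkage, km, B_ref = B_ref_gap,
                          seed = derive_seed(seed, "gap")),
      CCC = criterion_ccc(cp$B_k / cp$total,
                          expected_r2_reference(cp$xw, linkage, km,
                                                "hypercube", B_ref_ccc,
                                                derive_seed(seed, "ccc")),
                          n, p, km, "CCC"),
      CCCm = criterion_ccc(cp$B_k / cp$total,
                           expected_r2_reference(cp$xw, linkage, km,
                                                 "pca_box", B_ref_ccc,
                                                 derive_seed(seed, "cccm")),
                           n, p, km, "CCCm"),
      gDGC = gdgc_from_path(cp, alpha = alpha, B_null = B_null,
                            seed = null_seed %||% derive_seed(seed, "gdgc"),
                            cache = null_cache)
    )
  }
  k_hat <- unname(vapply(series, function(s)
    as.integer(if (inherits(s, "gdgc_result")) s$k else s$k_hat), integer(1)))
  flag <- unname(vapply(series, function(s)
    if (inherits(s, "gdgc_result")) NA_character_ else s$flag, character(1)))
  structure(
    list(summary = tibble::tibble(method = names(series), k_hat = k_hat,
                                  flag = flag),
         series = series, path = cp,
         params = list(linkage = linkage, alpha = alpha, B_null = B_null,
                       B_ref_gap = B_ref_gap, B_ref_ccc = B_ref_ccc,
                       kmax = km, seed = seed)),
    class = "k_estimate")
}

#' @export
print.k_estimate <- function(x, ...) {
  cat(sprintf("<k_estimate> linkage = %s, Kmax = %d\n",
              x$params$linkage, x$params$kmax))
  print(x$summary)
  invisible(x)
}
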