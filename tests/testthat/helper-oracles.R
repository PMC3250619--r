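# Independent oracles used across tests. These deliberately re-derive the
# quantities with naive loops so they share no code with the implementation.

# O(n^3) agglomeration recomputing the cross-pair linkage from the ORIGINAL
# leaf distances at every step. Ties: merge the pair with lexicographically
# smallest leader indices.
naive_agglomerate <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    best_val <- Inf
    m <- length(clusters)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      val <- if (linkage == "average") mean(cross) else max(cross)
      if (val < best_val - 1e-15) {
        best_val <- val
        best <- c(i, j)
      }
    }
    heights[step] <- best_val
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# loop-based within/between scatter for a partition
naive_scatter <- function(x, labels) {
  x <- as.matrix(x)
  p <- ncol(x)
  grand <- colMeans(x)
  W <- B <- matrix(0, p, p)
  for (g in sort(unique(labels))) {
    rows <- x[labels == g, , drop = FALSE]
    cm <- colMeans(rows)
    for (i in seq_len(nrow(rows))) {
      dv <- rows[i, ] - cm
      W <- W + outer(dv, dv)
    }
    db <- cm - grand
    B <- B + nrow(rows) * outer(db, db)
  }
  tot <- 0
  for (i in seq_len(nrow(x))) tot <- tot + sum((x[i, ] - grand)^2)
  list(W = W, B = B, W_k = sum(diag(W)), B_k = sum(diag(B)), total = tot)
}

# independent Monte-Carlo E(R^2) under the uniform-hypercube null
naive_expected_r2 <- function(x, k, B_ref, seed, linkage = "average") {
  set.seed(seed)
  n <- nrow(x)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  r2 <- numeric(B_ref)
  for (b in seq_len(B_ref)) {
    z <- sapply(seq_len(ncol(x)), function(j) runif(n, lo[j], hi[j]))
    lab <- cutree(hclust(dist(z), method = linkage), k = k)
    sc <- naive_scatter(z, lab)
    r2[b] <- sc$B_k / sc$total
  }
  r2
}

random_expr_mat <- function(G = 10, T_treat = 3, N_rep = 3, seed = 1,
                            sd = 1, shift = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(G * T_treat * N_rep, sd = sd), G)
  if (!is.null(shift)) v <- v + shift
  expression_matrix(
    v,
    treatment = rep(paste0("T", seq_len(T_treat)), each = N_rep),
    replicate = rep(seq_len(N_rep), times = T_treat))
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  as.matrix(dist(matrix(rnorm(n * 3), n)))
}
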