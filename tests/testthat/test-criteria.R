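# shared tiny fixture: 1-D points 0, 0.1, 2, 2.1
tiny_path <- function() {
  x <- matrix(c(0, 0.1, 2, 2.1), 4, 1)
  tree <- hclust(dist(x), method = "average")
  tp <- genecut:::trace_path(x, cutree(tree, k = 1:4))
  list(x = x, tree = tree, tp = tp)
}

test_that("Calinski-Harabasz reproduces the hand computation", {
  tp <- tiny_path()$tp
  expect_equal(tp$W_k[2], 0.01)
  expect_equal(tp$B_k[2], 4)
  ch <- criterion_ch(tp$W_k, tp$B_k, n = 4, kmax = 3)
  expect_equal(ch$scores[1], 800)       # CH(2) = (4/1)/(0.01/2)
  expect_equal(ch$k_hat, 2L)

  # duplicated points: zero within-scatter scores +Inf and is flagged
  xd <- matrix(c(0, 0, 5, 5), 4, 1)
  treed <- hclust(dist(xd), method = "average")
  tpd <- genecut:::trace_path(xd, cutree(treed, k = 1:4))
  chd <- criterion_ch(tpd$W_k, tpd$B_k, 4, 3)
  expect_true(is.infinite(chd$scores[1]))
  expect_equal(chd$flag, "infinite_score")

  # all-identical data are degenerate
  expect_error(criterion_ch(c(0, 0, 0), c(0, 0, 0), 4, 3),
               class = "genecut_degenerate_error")
})

test_that("Hartigan statistic and threshold rule follow the definition", {
  tp <- tiny_path()$tp
  h <- criterion_hartigan(tp$W_k, n = 4, kmax = 3)
  expect_equal(h$scores[1], (4.01 / 0.01 - 1) * 2)   # H(1) = 800
  expect_equal(h$k_hat, 2L)

  # W(k) = W(k+1) gives H(k) = 0
  expect_equal(criterion_hartigan(c(5, 5, 1, 1), 10, 3)$scores[1], 0)
  expect_equal(criterion_hartigan(c(5, 5, 1, 1), 10, 3)$k_hat, 1L)

  # rule never satisfied: flagged unresolved at kmax
  w <- 100 * 2^-(0:5)                                 # H(k) always >= 10
  hu <- criterion_hartigan(w, n = 40, kmax = 5)
  expect_equal(hu$k_hat, 5L)
  expect_equal(hu$flag, "unresolved")
})

test_that("CH, H and Silh selections match naive evaluation of every cut", {
  for (s in 1:5) {
    set.seed(600 + s)
    x <- rbind(matrix(rnorm(10), 5, 2), matrix(rnorm(10, 4), 5, 2))
    tree <- hclust(dist(x), method = "average")
    kmax <- 8L
    cuts <- cutree(tree, k = 1:(kmax + 1))
    tp <- genecut:::trace_path(x, cuts)
    naive_W <- naive_B <- numeric(kmax + 1)
    for (k in 1:(kmax + 1)) {
      sc <- naive_scatter(x, cuts[, k])
      naive_W[k] <- sc$W_k; naive_B[k] <- sc$B_k
    }
    ks <- 2:kmax
    naive_ch <- (naive_B[ks] / (ks - 1)) / (naive_W[ks] / (10 - ks))
    expect_equal(criterion_ch(tp$W_k, tp$B_k, 10, kmax)$k_hat,
                 ks[which.max(naive_ch)])
    naive_h <- (naive_W[1:kmax] / naive_W[2:(kmax + 1)] - 1) * (10 - (1:kmax) - 1)
    naive_sel <- which(naive_h < 10)[1]
    expect_equal(criterion_hartigan(tp$W_k, 10, kmax)$k_hat, naive_sel)
    d <- as.matrix(dist(x))
    naive_sil <- sapply(ks, function(k) {
      mean(cluster::silhouette(cuts[, k], dmatrix = d)[, "sil_width"])
    })
    expect_equal(criterion_silhouette(d, cuts, kmax)$k_hat,
                 ks[which.max(naive_sil)])
  }
})

test_that("silhouette widths follow the definition and its bounds", {
  d <- as.matrix(dist(c(0, 0.1, 2)))
  s <- genecut:::silhouette_widths(d, c(1L, 1L, 2L))
  expect_equal(unname(s[1]), (2 - 0.1) / 2)      # a = 0.1, b = 2
  expect_equal(unname(s[3]), 0)                  # singleton convention

  # equidistant point scores zero
  d2 <- as.matrix(dist(c(0, 1, 2, 3)))
  s2 <- genecut:::silhouette_widths(d2, c(1L, 1L, 2L, 2L))
  expect_true(all(abs(s2) <= 1))

  for (s in 1:10) {
    set.seed(700 + s)
    x <- matrix(rnorm(30), 15, 2)
    d <- as.matrix(dist(x))
    lab <- cutree(hclust(as.dist(d), "average"), k = sample(2:6, 1))
    w <- genecut:::silhouette_widths(d, lab)
    expect_true(all(w >= -1 & w <= 1))
    if (min(table(lab)) > 1) {
      ref <- cluster::silhouette(lab, dmatrix = d)[, "sil_width"]
      expect_equal(unname(w), unname(ref), tolerance = 1e-10)
    }
  }
})

test_that("expected R^2 under the uniform null behaves at the extremes", {
  set.seed(8)
  x <- matrix(rnorm(16), 8, 2)
  e <- expected_r2_reference(x, "average", kmax = 8, null = "hypercube",
                             B_ref = 20, seed = 5)
  expect_equal(e[1], 0)                          # k = 1: no between scatter
  expect_equal(e[8], 1)                          # k = n: perfect fit
  expect_true(all(diff(e) >= -1e-10))            # nested cuts only gain R^2

  expect_error(
    expected_r2_reference(matrix(1, 5, 2), "average", 3, "hypercube", 10, 1),
    class = "genecut_degenerate_error")
})

test_that("Monte-Carlo E(R^2) agrees with an independent implementation", {
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2)
  B <- 150L
  ours <- expected_r2_reference(x, "average", kmax = 3, null = "hypercube",
                                B_ref = B, seed = 11)[3]
  naive <- naive_expected_r2(x, k = 3, B_ref = B, seed = 202)
  tol <- 3 * sd(naive) * sqrt(2 / B)
  expect_lt(abs(ours - mean(naive)), tol)
})

test_that("CCC scoring and the no-evidence rule follow the published form", {
  # R^2 equal to its null expectation scores zero everywhere -> k_hat = 1
  r2 <- c(0, 0.3, 0.5, 0.6)
  ccc0 <- criterion_ccc(r2, r2, n = 20, p = 2, kmax = 4)
  expect_equal(ccc0$scores, rep(0, 3))
  expect_equal(ccc0$k_hat, 1L)
  expect_equal(ccc0$flag, "no_evidence")

  # hand check of the scaling at one k
  ccc1 <- criterion_ccc(c(0, 0.8, 0.9), c(0, 0.5, 0.6), n = 20, p = 2,
                        kmax = 3)
  expect_equal(ccc1$scores[1],
               log((1 - 0.5) / (1 - 0.8)) * sqrt(20 * 1 / 2) / (0.501)^1.2)
  # p* caps at p
  expect_equal(ccc1$scores[2],
               log((1 - 0.6) / (1 - 0.9)) * sqrt(20 * 2 / 2) / (0.601)^1.2)
})

test_that("CCC recovers two well-separated clusters", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- rbind(matrix(rnorm(30 * 2), 30, 2),
               matrix(rnorm(30 * 2, mean = 6), 30, 2))
    tree <- hclust(dist(x), method = "average")
    tp <- genecut:::trace_path(x, cutree(tree, k = 1:11))
    e <- expected_r2_reference(x, "average", 10, "hypercube", B_ref = 50,
                               seed = 5000 + s)
    cc <- criterion_ccc(tp$B_k / tp$total, e, n = 60, p = 2, kmax = 10)
    if (cc$k_hat == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("the gap one-standard-error rule fires at the stated k", {
  expect_equal(genecut:::gap_select(c(0.10, 0.50, 0.52), c(NA, 0.04, 0.05)),
               2L)
  expect_equal(genecut:::gap_select(c(0.5, 0.3), c(0.01, 0.01)), 1L)
  expect_true(is.na(genecut:::gap_select(c(0, 0.5, 1), c(0.01, 0.01, 0.01))))
})

test_that("gap is centred near zero when the data match the reference null", {
  set.seed(12)
  x <- matrix(runif(40 * 2, -1, 1), 40, 2)
  tree <- hclust(dist(x), method = "average")
  tp <- genecut:::trace_path(x, cutree(tree, k = 1:9))
  g <- criterion_gap(x, tp$W_k, "average", kmax = 8, B_ref = 100, seed = 13)
  expect_true(all(abs(g$scores) < 4 * tidy(g)$s))
})

test_that("gap agrees with cluster::clusGap (d.power = 2, PCA box)", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40 * 2), 40, 2), matrix(rnorm(20 * 2, 4), 20, 2))
  tree <- hclust(dist(x), method = "average")
  tp <- genecut:::trace_path(x, cutree(tree, k = 1:9))
  hfun <- function(xx, k) list(cluster = cutree(hclust(dist(xx), "average"), k))
  cg <- cluster::clusGap(x, hfun, K.max = 8, B = 200, d.power = 2,
                         spaceH0 = "scaledPCA", verbose = FALSE)
  # identical observed path: clusGap's W is ours over 2, exactly
  expect_equal(log(tp$W_k[1:8]) - cg$Tab[, "logW"], rep(log(2), 8),
               ignore_attr = TRUE, tolerance = 1e-10)
  g <- criterion_gap(x, tp$W_k, "average", kmax = 8, B_ref = 200, seed = 7)
  expect_equal(g$scores, unname(cg$Tab[, "gap"]), tolerance = 0.06)
})

test_that("gap recovers two well-separated clusters", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- rbind(matrix(rnorm(30 * 2), 30, 2),
               matrix(rnorm(30 * 2, mean = 6), 30, 2))
    tree <- hclust(dist(x), method = "average")
    tp <- genecut:::trace_path(x, cutree(tree, k = 1:11))
    g <- criterion_gap(x, tp$W_k, "average", kmax = 10, B_ref = 50,
                       seed = 6000 + s)
    if (g$k_hat == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("estimate_k dispatches gDGC identically to calling it directly", {
  x <- random_expr_mat(20, 3, 3, seed = 31)
  est <- estimate_k(x, methods = "gDGC", B_null = 200, seed = 1,
                    null_seed = 42)
  direct <- gdgc_test(x, alpha = 0.05, B_null = 200, seed = 42)
  expect_equal(est$series$gDGC$Q_observed, direct$Q_observed)
  expect_equal(est$series$gDGC$Q_critical, direct$Q_critical)
  expect_equal(est$summary$k_hat[est$summary$method == "gDGC"], direct$k)
})

test_that("pure noise yields no CCC evidence of clusters", {
  x <- random_expr_mat(30, 3, 3, seed = 57)
  est <- estimate_k(x, methods = "CCC", B_ref_ccc = 50, seed = 2)
  expect_equal(est$summary$k_hat, 1L)
  expect_equal(est$summary$flag, "no_evidence")
})

test_that("rotating whitened coordinates leaves gap selections unchanged", {
  set.seed(64)
  x <- rbind(matrix(rnorm(20 * 3), 20, 3), matrix(rnorm(20 * 3, 3), 20, 3))
  qr_m <- qr.Q(qr(matrix(rnorm(9), 3)))
  xr <- x %*% qr_m
  sel <- function(z, seed) {
    tree <- hclust(dist(z), method = "average")
    tp <- genecut:::trace_path(z, cutree(tree, k = 1:9))
    criterion_gap(z, tp$W_k, "average", 8, B_ref = 50, seed = seed)$k_hat
  }
  ks <- sapply(1:20, function(s) sel(x, s))
  ks_rot <- sapply(1:20, function(s) sel(xr, s))
  # PCA-aligned reference makes the selection rotation invariant in
  # distribution (axis signs may reorder individual draws)
  expect_equal(sort(ks), sort(ks_rot))
})
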