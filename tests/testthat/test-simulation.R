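test_that("double centring removes additive row and column structure", {
  r <- residualize_gem(matrix(c(1, 3, 2, 4), 2))
  expect_equal(unname(r$values), matrix(2.5, 2, 2))

  # any purely additive matrix collapses to a constant
  g <- rnorm(6); m <- rnorm(4)
  y <- 3 + outer(g, rep(1, 4)) + outer(rep(1, 6), m)
  r2 <- residualize_gem(y)
  expect_equal(max(r2$values) - min(r2$values), 0, tolerance = 1e-12)

  # row and column means equal the grand mean
  set.seed(2)
  r3 <- residualize_gem(matrix(rnorm(200, sd = 3), 20))
  gm <- mean(r3$values)
  expect_equal(unname(rowMeans(r3$values)), rep(gm, 20), tolerance = 1e-8)
  expect_equal(unname(colMeans(r3$values)), rep(gm, 10), tolerance = 1e-8)

  expect_error(residualize_gem(matrix(1, 1, 5)),
               class = "genecut_argument_error")
})

test_that("the synthetic residual matrix obeys its construction", {
  r <- synthesize_rgem(400, 10, seed = 6)
  gm <- mean(r$values)
  expect_equal(unname(rowMeans(r$values)), rep(gm, 400), tolerance = 1e-8)
  expect_identical(r$values, synthesize_rgem(400, 10, seed = 6)$values)
  expect_false(identical(r$values, synthesize_rgem(400, 10, seed = 7)$values))

  # degenerate scale law: row SDs are computed around each row's own mean,
  # so only the column centring shrinks them, by (1 - 1/rows) ~ 1
  r1 <- synthesize_rgem(3830, 10, sdlog = 0, seed = 8)
  rms <- sqrt(mean(r1$row_scale^2))
  expect_equal(rms, sqrt(1 - 1 / 3830), tolerance = 0.01)
})

test_that("cluster allocation is uniform with the minimum-size guard", {
  expect_equal(allocate_clusters(10, 1, seed = 1), rep(1L, 10))
  expect_error(allocate_clusters(3, 2), class = "genecut_argument_error")
  sizes <- replicate(200, {
    tab <- tabulate(allocate_clusters(100, 10), nbins = 10)
    expect_gte(min(tab), 2L)
    tab
  })
  expect_equal(mean(sizes), 10, tolerance = 0.2)
})

test_that("profiles are uniform on (-3, 3) and deterministic under a seed", {
  p <- generate_profiles(4, 3, seed = 9)
  expect_equal(dim(p), c(4L, 3L))
  expect_true(all(p > -3 & p < 3))
  expect_identical(p, generate_profiles(4, 3, seed = 9))

  set.seed(10)
  draws <- as.vector(generate_profiles(1000, 10))
  ks <- suppressWarnings(ks.test(draws, "punif", -3, 3))
  expect_gt(ks$p.value, 0.001)
})

test_that("simulated datasets have the declared shape and pass validation", {
  rg <- synthesize_rgem(300, 10, seed = 1)
  scn <- scenario(G = 40, k = 3, T_treat = 5, N_rep = 3)
  ds <- simulate_sgem(rg, scn, seed = 2)
  expect_s3_class(ds$x, "expr_mat")
  expect_equal(dim(ds$x), c(40L, 15L))
  expect_equal(ds$x$T_treat, 5L)
  expect_equal(ds$x$N_rep, 3L)
  expect_equal(sort(unique(unname(ds$labels))), 1:3)
  expect_true(all(tabulate(ds$labels) >= 2))
  expect_true(all(ds$profiles > -3 & ds$profiles < 3))
  # determinism
  ds2 <- simulate_sgem(rg, scn, seed = 2)
  expect_identical(ds$x$values, ds2$x$values)
  # infeasible requests fail
  expect_error(simulate_sgem(rg, scenario(400, 2, 3, 3), seed = 1),
               class = "genecut_argument_error")
})

test_that("treatment-mean contrasts recover the scaled profiles", {
  rg <- synthesize_rgem(2000, 10, seed = 3)
  prof <- rbind(c(-3, 3, 0), c(3, -3, 0))
  scn <- scenario(G = 200, k = 2, T_treat = 3, N_rep = 6)
  # per-gene scale variant: the effect added to gene i is delta * s_i, so
  # the T1 - T2 mean contrast recovers (delta_1 - delta_2) * s_i
  ds <- simulate_sgem(rg, scn, seed = 4, profiles = prof, scale = "gene")
  m <- treatment_means(ds$x)
  expected <- (ds$profiles[ds$labels, 1] - ds$profiles[ds$labels, 2]) *
    ds$gene_scale
  fit <- lm(I(m[, 1] - m[, 2]) ~ 0 + expected)
  expect_equal(unname(coef(fit)), 1, tolerance = 0.05)

  # common-scale variant: every gene carries the pooled residual SD
  dc <- simulate_sgem(rg, scn, seed = 5, profiles = prof, scale = "common")
  expect_equal(length(unique(dc$gene_scale)), 1L)
  mc <- treatment_means(dc$x)
  diffc <- (mc[, 1] - mc[, 2]) * ifelse(dc$labels == 1, -1, 1)
  expect_equal(unname(mean(diffc) / dc$gene_scale[1]), 6, tolerance = 0.1)
})

test_that("bootstrap noise preserves the source rows' first two moments", {
  rg <- synthesize_rgem(50, 10, seed = 11)
  row <- rg$values[7, ]
  ctr <- row - mean(row)
  set.seed(12)
  draws <- replicate(1000, sample(ctr, 30, replace = TRUE))
  # mean of resampled noise centres on zero
  expect_lt(abs(mean(draws)), 3 * sd(ctr) / sqrt(30000))
  # variance centres on the population variance of the atoms
  pop_var <- mean(ctr^2)
  vars <- apply(draws, 2, function(v) mean(v^2))
  expect_lt(abs(mean(vars) - pop_var), 3 * sd(vars) / sqrt(1000))
})

test_that("genes sharing a cluster share the nonscaled profile", {
  rg <- synthesize_rgem(300, 10, seed = 13)
  ds <- simulate_sgem(rg, scenario(30, 4, 3, 3), seed = 14)
  expect_equal(nrow(ds$profiles), 4L)
  # profiles differ across clusters almost surely
  expect_equal(nrow(unique(round(ds$profiles, 10))), 4L)
})

test_that("the scenario grid runner is a deterministic bookkeeper", {
  rg <- synthesize_rgem(200, 10, seed = 15)
  grid <- scenario_grid(G = 30, k = 2, T_treat = 3, N_rep = 3, reps = 2)
  res <- run_scenario_grid(rg, grid, methods = c("CH", "Silh"), seed = 8)
  expect_equal(nrow(res), 4L)
  expect_setequal(unique(res$method), c("CH", "Silh"))
  expect_equal(res$bias, res$k_hat - res$k)
  res2 <- run_scenario_grid(rg, grid, methods = c("CH", "Silh"), seed = 8)
  expect_identical(res, res2)

  # the default grid is the full 16-scenario factorial
  expect_equal(nrow(scenario_grid()), 16L)
})
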