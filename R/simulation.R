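#' Residualise a gene-expression matrix
#'
#' Removes additive row (gene) and column (array) effects by double
#' centring, then adds back the grand mean: `r_ij = y_ij - rowmean_i -
#' colmean_j + 2 * grandmean`. Under the additive model
#' `Y_ij = mu + g_i + m_j + e_ij` of a self-self experiment, the result is
#' pure noise around the grand mean; its rows supply gene-specific noise
#' scales and resampling pools for the simulator. Every row mean and column
#' mean of the output equals the grand mean.
#'
#' @param y Numeric matrix with at least 2 rows and 2 columns.
#' @return A `residual_gem`: list with `values` and the per-row SD
#'   `row_scale`.
#' @export
residualize_gem <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) < 2L || ncol(y) < 2L)
    stop_genecut("need at least a 2 x 2 matrix", "genecut_argument_error")
  grand <- mean(y)
  r <- y - rowMeans(y) - rep(colMeans(y), each = nrow(y)) + 2 * grand
  structure(list(values = r, row_scale = apply(r, 1L, stats::sd)),
            class = "residual_gem")
}

#' Synthesise a residual gene-expression matrix
#'
#' Stand-in generator for the residual matrix of a self-self microarray
#' experiment: per-row noise SDs are drawn from a log-normal scale law
#' (heavier-tailed spread of per-gene variability, as seen in microarray
#' residuals), rows are filled with independent normal noise at that scale,
#' and the result is passed through [residualize_gem()]. Defaults emulate a
#' 3830 x 10 residual matrix.
#'
#' @param rows,cols Matrix dimensions.
#' @param meanlog,sdlog Parameters of the log-normal row-SD law.
#' @param seed Optional integer seed.
#' @return A `residual_gem` (synthetic).
#' @export
synthesize_rgem <- function(rows = 3830L, cols = 10L, meanlog = 0,
                            sdlog = 0.5, seed = NULL) {
  if (rows < 2L || cols < 2L)
    stop_genecut("need rows >= 2 and cols >= 2", "genecut_argument_error")
  gen <- function() {
    s <- stats::rlnorm(rows, meanlog = meanlog, sdlog = sdlog)
    matrix(stats::rnorm(rows * cols, sd = rep(s, cols)), rows, cols)
  }
  y <- if (is.null(seed)) gen() else with_seed(seed, gen())
  residualize_gem(y)
}

#' @export
print.residual_gem <- function(x, ...) {
  cat(sprintf("<residual_gem> %d x %d, median row SD %.3f\n",
              nrow(x$values), ncol(x$values), stats::median(x$row_scale)))
  invisible(x)
}

#' Simulation scenario
#'
#' One cell of the benchmark grid: `G` candidate genes carrying `k` true
#' clusters across `T` treatments with `N` replicates.
#'
#' @param G Genes. @param k True clusters. @param T_treat Treatments.
#' @param N_rep Replicates.
#' @return A `scenario` list.
#' @export
scenario <- function(G, k, T_treat, N_rep) {
  if (G < 2L * k)
    stop_genecut("infeasible scenario: need G >= 2k", "genecut_argument_error")
  if (min(G, k, T_treat, N_rep) < 1L || N_rep < 2L || T_treat < 2L)
    stop_genecut("invalid scenario dimensions", "genecut_argument_error")
  structure(list(G = as.integer(G), k = as.integer(k),
                 T_treat = as.integer(T_treat), N_rep = as.integer(N_rep)),
            class = "scenario")
}

#' Random cluster allocation
#'
#' Assigns each of `G` genes independently and uniformly to one of `k`
#' clusters, redrawing until every cluster holds at least 2 genes.
#'
#' @param G Genes. @param k Clusters. @param seed Optional seed.
#' @return Integer labels of length `G`.
#' @export
allocate_clusters <- function(G, k, seed = NULL) {
  if (G < 2L * k)
    stop_genecut("infeasible: need G >= 2k", "genecut_argument_error")
  draw <- function() {
    repeat {
      lab <- sample.int(k, G, replace = TRUE)
      if (k == 1L || min(tabulate(lab, nbins = k)) >= 2L) return(lab)
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Random cluster profiles of treatment effects
#'
#' Non-scaled treatment-effect profiles, one row per cluster, entries drawn
#' independently and uniformly on (-3, 3). Genes in a cluster share its
#' profile, scaled by their own within-gene SD, so treatment-mean
#' differences range between -3 and +3 within-SD units.
#'
#' @param k Clusters. @param T_treat Treatments. @param seed Optional seed.
#' @return `k x T` numeric matrix.
#' @export
generate_profiles <- function(k, T_treat, seed = NULL) {
  gen <- function() matrix(stats::runif(k * T_treat, -3, 3), k, T_treat)
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a candidate-gene expression matrix with known clusters
#'
#' For each simulated gene: a source row of the residual matrix is sampled
#' without replacement; the gene's within-SD is that row's scale; its
#' `T * N` noise values are resampled with replacement from the row's
#' centred entries (preserving any non-normality of the residuals); the
#' observed value for treatment `t`, replicate `r` is
#' `rowmean + profile[cluster, t] * s_i + noise`. Cluster labels come from
#' [allocate_clusters()] and profiles from [generate_profiles()] unless
#' supplied.
#'
#' @param rgem A `residual_gem` (real, via [residualize_gem()], or
#'   synthetic via [synthesize_rgem()]).
#' @param scn A [scenario()].
#' @param seed Optional integer seed.
#' @param labels,profiles Optional fixed truth (otherwise drawn).
#' @param noise `"bootstrap"` (default: resample centred source-row
#'   entries) or `"gaussian"` (normal noise at the gene's scale).
#' @param scale `"common"` (default) or `"gene"`. With `"common"`, every
#'   simulated gene carries the residual matrix's pooled within-SD: source
#'   rows are standardised before resampling and effects are scaled by the
#'   pooled SD, so the candidate genes share a common within-gene scale, as
#'   the pooled-covariance Mahalanobis analysis assumes. With `"gene"`, each
#'   gene keeps its source row's own SD for both noise and effect scaling;
#'   heterogeneous scales then distort the pooled geometry and every
#'   estimator over-partitions (see the package vignette).
#' @return List with `x` (an [expression_matrix()]), `labels`, `profiles`,
#'   `gene_scale`, and the scenario.
#' @export
simulate_sgem <- function(rgem, scn, seed = NULL, labels = NULL,
                          profiles = NULL, noise = c("bootstrap", "gaussian"),
                          scale = c("common", "gene")) {
  stopifnot(inherits(rgem, "residual_gem"), inherits(scn, "scenario"))
  noise <- match.arg(noise)
  scale <- match.arg(scale)
  if (scn$G > nrow(rgem$values))
    stop_genecut("scenario asks for more genes than residual rows",
                 "genecut_argument_error")
  s_pooled <- sqrt(mean(rgem$row_scale^2))
  gen <- function() {
    lab <- labels %||% allocate_clusters(scn$G, scn$k)
    prof <- profiles %||% generate_profiles(scn$k, scn$T_treat)
    src <- sample.int(nrow(rgem$values), scn$G, replace = FALSE)
    H <- scn$T_treat * scn$N_rep
    vals <- matrix(0, scn$G, H)
    s_i <- if (scale == "gene") rgem$row_scale[src]
           else rep(s_pooled, scn$G)
    for (g in seq_len(scn$G)) {
      row <- rgem$values[src[g], ]
      ctr <- row - mean(row)
      if (scale == "common") ctr <- ctr * (s_pooled / stats::sd(row))
      eps <- if (noise == "bootstrap")
        sample(ctr, H, replace = TRUE)
      else stats::rnorm(H, sd = s_i[g])
      effect <- rep(prof[lab[g], ], each = scn$N_rep)
      vals[g, ] <- mean(row) + effect * s_i[g] + eps
    }
    x <- expression_matrix(
      vals,
      treatment = rep(paste0("T", seq_len(scn$T_treat)), each = scn$N_rep),
      replicate = rep(seq_len(scn$N_rep), times = scn$T_treat),
      gene_ids = paste0("gene_", seq_len(scn$G)))
    list(x = x, labels = stats::setNames(lab, x$gene_ids), profiles = prof,
         gene_scale = stats::setNames(s_i, x$gene_ids), scenario = scn)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' The benchmark scenario grid
#'
#' Full factorial over genes, true clusters, treatments and replicates. The
#' defaults are the study conditions of the benchmark: `G` in (100, 300),
#' `k` in (2, 10), `T` in (3, 5), `N` in (3, 6), i.e. 16 scenarios.
#'
#' @param G,k,T_treat,N_rep Factor levels.
#' @param reps Simulated datasets per scenario (default 10).
#' @return Tibble, one row per scenario, with a `reps` column.
#' @export
scenario_grid <- function(G = c(100L, 300L), k = c(2L, 10L),
                          T_treat = c(3L, 5L), N_rep = c(3L, 6L),
                          reps = 10L) {
  g <- expand.grid(G = G, k = k, T_treat = T_treat, N_rep = N_rep,
                   KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g) |> dplyr::mutate(reps = reps)
}

#' Run estimators over a scenario grid
#'
#' For every scenario and replicate, simulates a dataset from the residual
#' matrix, runs each requested estimator, and records
#' `bias = k_hat - k_true`. Per-dataset seeds are derived deterministically
#' from the master seed and the scenario, so any single dataset can be
#' regenerated in isolation; gDGC null distributions are cached across
#' same-shaped scenarios. Estimator failures are recorded as missing rows,
#' not raised.
#'
#' @param rgem A `residual_gem`.
#' @param grid Tibble from [scenario_grid()] (columns `G, k, T_treat, N_rep,
#'   reps`).
#' @param methods Estimators to run (see [estimate_k()]).
#' @param linkage `"average"` or `"complete"`.
#' @param seed Integer master seed.
#' @param alpha,B_null,B_ref_gap,B_ref_ccc,kmax Passed to [estimate_k()].
#' @return Tidy tibble: scenario fields, `rep`, `method`, `k_hat`, `bias`,
#'   `flag`, `error`. An unresolved selection rule (Hartigan or gap never
#'   firing below `Kmax`) keeps its `k_hat` but records `bias = NA`, so
#'   summaries exclude rather than impute it.
#' @export
run_scenario_grid <- function(rgem, grid, methods = c("gDGC", "CH", "H",
                                                      "CCC", "CCCm", "Silh",
                                                      "Gap"),
                              linkage = "average", seed = 1L, alpha = 0.05,
                              B_null = 1000L, B_ref_gap = 50L,
                              B_ref_ccc = 100L, kmax = NULL) {
  cache <- null_cache()
  out <- vector("list", nrow(grid) * max(grid$reps))
  pos <- 0L
  for (i in seq_len(nrow(grid))) {
    scn <- scenario(grid$G[i], grid$k[i], grid$T_treat[i], grid$N_rep[i])
    for (r in seq_len(grid$reps[i])) {
      ds_seed <- derive_seed(seed, "sgem", scn$G, scn$k, scn$T_treat,
                             scn$N_rep, r)
      ds <- simulate_sgem(rgem, scn, seed = ds_seed)
      est <- tryCatch(
        estimate_k(ds$x, methods = methods, linkage = linkage, alpha = alpha,
                   B_null = B_null, B_ref_gap = B_ref_gap,
                   B_ref_ccc = B_ref_ccc, kmax = kmax,
                   seed = derive_seed(seed, "est", scn$G, scn$k,
                                      scn$T_treat, scn$N_rep, r),
                   null_seed = derive_seed(seed, "nullq", scn$G,
                                           scn$T_treat, scn$N_rep),
                   null_cache = cache),
        error = function(e) e)
      row <- if (inherits(est, "error")) {
        tibble::tibble(method = methods, k_hat = NA_integer_,
                       flag = NA_character_, error = conditionMessage(est))
      } else {
        dplyr::mutate(est$summary, error = NA_character_)
      }
      pos <- pos + 1L
      # an unresolved selection rule is a missing estimate, not a value
      out[[pos]] <- dplyr::mutate(
        row, G = scn$G, k = scn$k, T_treat = scn$T_treat, N_rep = scn$N_rep,
        rep = r,
        bias = ifelse(!is.na(.data$flag) & .data$flag == "unresolved",
                      NA_real_, .data$k_hat - scn$k),
        .before = 1L)
    }
  }
  dplyr::bind_rows(out[seq_len(pos)]) |>
    dplyr::select("G", "k", "T_treat", "N_rep", "rep", "method", "k_hat",
                  "bias", "flag", "error")
}
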