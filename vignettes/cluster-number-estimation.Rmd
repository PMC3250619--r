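---
title: "Estimating the number of gene-expression clusters: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the number of gene-expression clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(genecut)
```

## The data model

`genecut` works on a candidate-gene expression matrix: `G` genes (rows)
measured on `H = T × N` arrays, `T` treatment conditions with `N` biological
replicates each, in log-expression units. Two summaries drive everything
else:

* the mean-profile matrix: row `i` is `ȳ_i`, the vector of per-treatment
  means of gene `i` (`G × T`);
* the pooled within-gene covariance
  `S = Σ_i Σ_r (y_ir − ȳ_i)(y_ir − ȳ_i)' / (G(N − 1))`,
  where `y_ir` is the `T`-vector collecting replicate `r` of gene `i`
  across treatments.

Replicate index `r` pairs columns across treatments when forming `y_ir`, so
`S` can carry covariances between treatments measured in the same
hybridisation batch; `pooled_within_covariance(x, type = "diagonal")` pools
only per-treatment variances for designs where replicates are not paired.

Gene dissimilarity is the Mahalanobis distance
`D_ij = sqrt((ȳ_i − ȳ_j)' S^{-1} (ȳ_i − ȳ_j))`. For the sum-of-squares
criteria the same geometry is obtained by whitening: with
`x̃_i = S^{-1/2} ȳ_i` (symmetric inverse square root), Euclidean distances
among the `x̃_i` equal the `D_ij`. The package deliberately standardises by
`S`, not by the covariance of a mean (`S/N`): a constant rescaling of all
distances cancels in the gDGC test (observed statistic and simulated null
scale together) and is invisible to CH, Hartigan, CCC, silhouette and gap,
which are all scale-free; fixing one convention keeps every method "applied
to the same distance matrix".

If `S` is numerically singular (possible when `T > G(N − 1)` or with
degenerate input) a ridge `1e-8 · mean(diag(S)) · I` is added with a
warning; pass `ridge = NULL` to make this an error instead.

## One tree, many rules

All estimators score the partitions obtained by cutting a single
agglomerative tree (average linkage by default, i.e. UPGMA: merge the pair
of clusters with the smallest unweighted mean of cross-pair leaf distances;
or complete linkage) at `k = 1 … Kmax` clusters, with
`Kmax = min(20, G − 1)` by default. Cutting one tree, rather than re-running
a flat clusterer per `k`, matches the hierarchical practice the package
supports and makes the criteria directly comparable. Agglomeration is
delegated to `stats::hclust`, whose average/complete methods implement
exactly these definitions; the test suite pins them against a naive
implementation that recomputes cross-pair linkage from the original leaf
distances at every step. Tie-breaking between equal linkage values follows
`hclust`; with continuous expression data ties have probability zero.

With `Z` the `n × k` indicator of a partition and `X` the whitened
profiles, the criteria use the scatter decomposition
`C = (Z'Z)^{-1} Z'X`, `W = (X − ZC)'(X − ZC)`, and a **centred** between
matrix `B = Σ_r n_r (c_r − x̄)(c_r − x̄)'`. Centring matters: the raw cross
product `C'Z'ZC` does not satisfy `W + B = total` and would leave `B(1) ≠ 0`,
breaking every rule that reads `B(k)/total` as explained variance. The
traces `W(k) = tr W`, `B(k) = tr B` obey `W(k) + B(k) = total` to 1e-8 on
every fixture in the test suite.

Selection rules, with their numerical choices:

* **CH** maximises `[B(k)/(k−1)] / [W(k)/(n−k)]` over `k = 2 … Kmax`; a cut
  with `W(k) = 0` scores `+Inf` and is flagged.
* **Hartigan** takes the smallest `k ≥ 1` with
  `[(W(k)/W(k+1)) − 1](n − k − 1) < 10`; if the rule never fires the series
  is flagged `unresolved` and treated as a missing estimate downstream.
* **CCC** uses Sarle's form
  `ln[(1 − E(R²))/(1 − R²)] · sqrt(n p*/2) / (0.001 + E(R²))^{1.2}` with
  `p* = min(k − 1, p)` (the between-cluster variation of `k` centred means
  spans at most `k − 1` dimensions; the data supply at most `p`). The
  square-root scaling is the one under which the conventional "max CCC < 2
  ⟹ no cluster evidence, report k = 1" threshold is calibrated. `E(R²)` is
  estimated by Monte Carlo — `B_ref` uniform datasets on the axis-aligned
  bounding hypercube of the whitened data, clustered with the same linkage
  — rather than by a closed-form approximation, for uniformity with the gap
  machinery and with the PCA-box variant `CCCm`, which differs only in
  drawing the reference uniformly on the box aligned with the principal
  components.
* **Silhouette** averages `s(i) = (b(i) − a(i))/max(a(i), b(i))` on the
  Mahalanobis distance matrix; a singleton cluster contributes `s(i) = 0`
  (the neutral convention). `k = 1` is not scoreable, so this method cannot
  report "no clusters".
* **Gap** compares `log W(k)` with its expectation under `B_ref` uniform
  draws on the PCA-aligned box (which keeps the procedure rotation
  invariant), and selects the smallest `k` with
  `gap(k) ≥ gap(k+1) − s(k+1)`, where `s(k)` is the reference standard
  deviation of `log W*(k)` inflated by `sqrt(1 + 1/B_ref)`. The
  implementation reproduces `cluster::clusGap(d.power = 2,
  spaceH0 = "scaledPCA")` to Monte-Carlo error (a test asserts this), but
  is kept in-package so the reference draws share the whitened geometry and
  seeding scheme.

Defaults: `B_ref = 50` for gap and `B_ref = 100` for CCC/CCCm, seedable and
derived per criterion from one master seed in `estimate_k()`.

## The gDGC test

The root-node distance `Q` — the height of the dendrogram's final merge —
is treated as a test statistic for the null hypothesis that all genes share
one population mean profile. Its null distribution is simulated: each
replicate draws `G × N` independent standard-normal `T`-vectors, forms gene
means and the pooled covariance exactly as the observed pipeline does,
whitens, agglomerates, and records the root height. Under multivariate
normality the Mahalanobis standardisation makes this distribution invariant
to the true within-gene covariance, so identity-covariance draws suffice;
re-estimating `S` in every replicate keeps the sampling noise of the
covariance inside the null, which matters at small `G(N − 1)`. In the
smallest case (`G = 2`, `T = 1`) the construction collapses to a two-sample
t statistic — `Q = sqrt(2/N) |t_{2(N−1)}|` — and the simulated 95% point is
tested against that closed form.

The critical value `Q_{1−α}` is the empirical `(1 − α)`-quantile of the
`B_null` simulated root distances (type-7 interpolation, the `quantile()`
default; `B_null = 1000` by default, with a warning below 100). If
`Q_observed ≥ Q_{1−α}` the tree is cut once, at height `Q_{1−α}`: the
reported groups are the maximal clusters all of whose internal merges sit
strictly below the critical height. Inner nodes are not re-tested
recursively — the cut is a single horizontal line, which keeps the
procedure's interpretation as one α-level test. Groups receive letter codes
`a, b, c, …` in dendrogram leaf order, the familiar display of multiple
mean comparisons. A consequence of the fixed-α cut worth knowing: even with
arbitrarily well-separated true clusters, a fraction ≈ α of analyses will
split one true cluster once more, so exact-partition recovery plateaus near
`1 − α`, not at 1.

Null distributions depend only on `(G, T, N, linkage, B_null, seed)` and are
the expensive part, so `null_cache()` lets repeated tests on same-shaped
data reuse one simulation; `null_table()` tabulates `Q_{1−α}` over design
grids for the same purpose. For non-normal data, `null = "bootstrap"`
resamples replicate-level residual vectors within genes instead of drawing
Gaussians.

## The simulation benchmark

The benchmark needs noise that looks like a microarray experiment in which
nothing is truly differentially expressed. Its source is a residual matrix:
`residualize_gem()` removes additive row (gene) and column (array) effects
by double centring and adds back the grand mean, which under the additive
model `Y_ij = μ + g_i + m_j + ε_ij` leaves pure noise around `μ`.
`synthesize_rgem()` builds a synthetic stand-in (default 3830 × 10): per-row
noise SDs from a log-normal law (log-mean 0, log-SD 0.5 — a realistic,
right-skewed spread of per-gene variability), Gaussian rows at those
scales, then the same double centring.

`simulate_sgem()` turns residual rows into a candidate-gene matrix with
known structure: each simulated gene takes a source row (sampled without
replacement), its `T × N` noise values are resampled with replacement from
the row's centred entries (preserving any non-normality; `noise =
"gaussian"` switches to normal draws), and a cluster-specific profile of
treatment effects — entries uniform on (−3, 3), shared by all genes in the
cluster — is added, scaled by the within-gene SD. Cluster labels are
uniform over `1 … k`, redrawn until every cluster has at least two genes.

The one genuinely open design choice is **whose** within-SD scales the
effects and noise, and the package's default is deliberate:

* `scale = "common"` (default): source rows are standardised and rescaled
  to the residual matrix's pooled SD, so every candidate gene carries a
  common within-gene scale and the effect added to a cluster's genes is
  identical in absolute units. This is the regime the analysis model
  assumes — a common pooled covariance across genes — and the regime in
  which the benchmark behaves like published bias studies of these
  estimators: near-unbiased testing-based cuts at `k = 2`, mild
  overestimation by index maximisers, underestimation by all methods at
  `k = 10`, and bias essentially independent of `N` when clusters are well
  separated.
* `scale = "gene"`: effects and noise keep each source row's own SD. The
  candidate set then mixes genes whose noise is several-fold above and
  below the pooled level; under a *pooled* Mahalanobis geometry the
  high-scale genes sit systematically far from everything and split off as
  spurious groups, within-cluster spread acquires a component that does not
  shrink with `N`, and every estimator over-partitions — with the gap rule
  collapsing to `k = 1` because the reference box inherits the same
  elongation. This variant is kept because it is informative about
  robustness: it shows precisely how pooled-covariance clustering degrades
  when the common-scale assumption is violated, and it argues for
  per-gene standardisation before any pooled-geometry analysis of real
  data with strongly heterogeneous variances.

What the generator does **not** emulate about real residual matrices:
correlations between arrays, intensity-dependent variance, heavy-tailed
outliers, or any dependence between genes. Estimator biases measured here
are therefore a clean-noise lower bound; on real residuals the
index-maximising methods (CH, gap, silhouette) can be expected to pick up
additional spurious structure and drift upward, and our benchmark indeed
sits slightly below older reported biases for exactly those methods, while
reproducing the testing-based and threshold-based methods closely. Passing
benchmarks here demonstrate correctness of the estimators and the expected
ordering of their biases, not performance guarantees on arbitrary arrays.

`run_scenario_grid()` executes a factorial grid (defaults
`G ∈ {100, 300} × k ∈ {2, 10} × T ∈ {3, 5} × N ∈ {3, 6}`, 10 datasets per
scenario) with per-dataset seeds derived deterministically from one master
seed, so any dataset can be regenerated in isolation; gDGC null
distributions are cached per design shape. Estimator failures become
missing rows; unresolved Hartigan/gap rules record `bias = NA` and are
excluded (never imputed) by `bias_summary()`, which reports per-group mean
bias, standard error and t-based 95% intervals. Because every method sees
the same datasets, intervals are correlated across methods — the rendered
report says so.

## Problem sizes used by the tests

The shipped suite exercises: the full `k = 2` grid (8 scenarios × 10
datasets, 6 estimators, `B_null = 1000`, gap `B_ref = 50`, CCC
`B_ref = 100`); the `k = 10` families for gDGC (`T = 5`) and gap (`T = 3`),
40 datasets each; test size over 500 null datasets at `G = 100, T = 3,
N = 3`; the t-limit check at `B_null = 20000`; and 100-seed recovery runs at
profile separation 6 within-SDs. These sizes were chosen to keep
Monte-Carlo error well inside the tolerances being asserted while remaining
comfortable on a single CPU.

## Known limitations

* The gDGC null assumes exchangeable replicate vectors per gene with a
  covariance common across genes; strong per-gene variance heterogeneity
  violates it and inflates the false-split rate (see `scale = "gene"`
  above). Standardise genes first, or use the bootstrap null.
* Estimates from cutting one tree inherit the tree's mistakes: none of the
  criteria can repair a bad early merge.
* `Kmax` caps every index maximiser; data whose true `k` exceeds `Kmax`
  surface as `unresolved`/capped selections, not as larger estimates.
* The silhouette cannot return `k = 1`, and CH is undefined there, so both
  overestimate by construction when the truth is a single cluster; CCC and
  gDGC are the methods with an explicit "no clusters" answer.
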