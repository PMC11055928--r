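# sdpgwr

Bayesian clustering of spatially varying regression coefficients for areal
data. `sdpgwr` fits a geographically weighted Gaussian regression whose
area-level coefficient vectors are grouped by a **spatial stick-breaking
Dirichlet process** prior: the number of clusters, the cluster map, and the
cluster-level coefficients are all inferred jointly, with full posterior
uncertainty. It is aimed at population-health and small-area analyses where
the question is *which regions share the same covariate effects* — not just
how effects vary smoothly.

## The model

For areas \(s_1, \dots, s_n\) with responses \(y(s_i)\) and covariates
\(x(s_i) \in \mathbb{R}^p\):

```
y(s_i) | z_i            ~  N( x(s_i)' beta_{z_i},  sigma^2(s_i) )
beta_k                  ~  N_p( mu_k, Sigma_k ),   (mu_k, Sigma_k) ~ NIW
P(z_i = k)              =  p_k(s_i)                 (spatial stick-breaking)
p_k(s)                  =  l_k(s) V_k  *  prod_{j<k} (1 - l_j(s) V_j)
V_k ~ Beta(a_v, b_v);   l_k(s): kernel at knot psi_k, bandwidth eps_k
```

The kernels (uniform box or squared exponential, fixed or random
bandwidths) make cluster membership spatially coherent; distance-decay
observation weights `w = 1 if d <= 1, exp(-d/b) otherwise` on the
contiguity-graph or great-circle distance matrix define the geographically
weighted likelihood variant. Inference is a blocked Gibbs /
Metropolis–Hastings sampler with a split–merge move; point cluster
configurations come from **Dahl's least-squares method** and the posterior
mode; models are compared with **WAIC** and scored against known partitions
with the **Rand index**.

## Worked example

Simulate the package's reference conditions — 159 lattice areas in three
regions of sizes 51/49/59 with six spatially correlated covariates — and
fit with a squared-exponential kernel, 9 knots and a truncation of 20:

```r
library(sdpgwr)

sim <- simulate_dataset(seed = 1)
sim
#> <sdp_sim> 159 areas, 6 covariates, 3 regions (51/49/59), noise sd 0.5

fit <- sdp_gwr(
  sim$data, sim$graph,
  sdp_gwr_config(stick = stick_config(kernel = "squared_exponential",
                                      bandwidth_prior = "fixed_lambda_sq_half",
                                      knots = 9, truncation = 20)),
  chain_config(n_iter = 2000, burn_in = 500, seed = 2))

labels <- cluster_labels(fit, "dahl")
table(labels$cluster)
#>  1  2  3
#> 50 59 50

rand_index(labels$cluster, sim$truth$cluster)
#> [1] 0.9190351

dplyr::filter(tidy(fit), term == "x1")
#> # A tibble: 3 x 7
#>   cluster  size term  estimate hpd_lower hpd_upper n_draws
#>     <int> <int> <chr>    <dbl>     <dbl>     <dbl>   <int>
#> 1       1    50 x1      -1.18     -1.32     -1.06     1500
#> 2       2    59 x1       2.29      1.98      2.58     1500
#> 3       3    50 x1       0.730     0.543     0.913    1500

glance(fit)[, c("n_clusters", "waic", "p_waic")]
#> # A tibble: 1 x 3
#>   n_clusters  waic p_waic
#>        <int> <dbl>  <dbl>
#> 1          3  286.   39.5
```

Three occupied clusters are recovered, with a Rand index of 0.92 against
the generating partition; the per-cluster coefficient table is read like a
regression summary per region — cluster 2's `x1` effect of 2.29 (95% HPD
1.98–2.58) against generating values of −1.0 / 0.62 / 2.31 per region. `autoplot(fit)` maps the Dahl configuration over the centroids,
`cluster_labels(fit, "mode")` gives the posterior-mode configuration, and
`run_replicate_study()` repeats simulate–fit–score end to end and aggregates
Rand indices and coefficient accuracy (MAB/MSD/MMSE).

A thin command-line interface (`inst/cli/sdpgwr`) exposes `simulate`, `fit`,
`summarize`, `replicate-study` and `metrics` subcommands over CSV area
tables, edge lists and YAML configs; every run writes a JSON manifest with
its seed, configuration and input digests.

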