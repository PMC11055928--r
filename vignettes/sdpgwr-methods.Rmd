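---
title: "Clustered coefficients for areal regression: model, sampler and design choices"
author: "sdpgwr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered coefficients for areal regression: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sdpgwr` fits a Bayesian regression for areal (lattice) data in which the
coefficient vector at each area is one of an unknown number of cluster-level
coefficient vectors, and cluster membership is spatially structured. This
vignette is the package's account of the model, the sampler, and every design
choice a maintainer or reviewer would want to see argued rather than just
coded.

## The model

Each area \(s_i\) carries a response \(y(s_i)\), covariates \(x(s_i) \in
\mathbb{R}^p\) and a latent label \(z_i \in \{1, \dots, K\}\):

\[
y(s_i) \mid z_i \sim \mathcal{N}\!\big(x(s_i)^\top \beta_{z_i},\ \sigma^2(s_i)\big),
\qquad
\Pr(z_i = k) = p_k(s_i).
\]

The cluster atoms have a conjugate hierarchical base measure,
\(\beta_k \sim \mathcal{N}_p(\mu_k, \Sigma_k)\),
\(\mu_k \mid \Sigma_k \sim \mathcal{N}_p(m, \Sigma_k)\),
\(\Sigma_k \sim \mathrm{IW}(D_0, c_0)\), and the variance field has an
inverse-gamma prior. The location-dependent mixture weights come from a
*spatial stick-breaking* construction truncated at \(K\): stick fractions
\(V_k \sim \mathrm{Beta}(a_v, b_v)\) are attenuated by a kernel centred at a
knot \(\psi_k\) with per-dimension bandwidths \(\varepsilon_k\),

\[
V_k(s) = l_k(s)\, V_k, \qquad
p_k(s) = V_k(s) \prod_{j<k} \big(1 - V_j(s)\big),
\]

with the final stick forced to one at every location so the weights sum to
one exactly by construction, not by division. Two kernel families are
provided — the uniform box kernel and the squared exponential — each with a
fixed or random bandwidth model (fixed at \(\lambda\), \(\mathrm{Exp}\) with
mean \(\lambda\), fixed at \(\lambda^2/2\), or
\(\mathrm{InvGamma}(1.5, \lambda^2/2)\)). Coordinates are affinely rescaled
to the unit square before kernel evaluation, so \(\lambda\) always lives on
that scale. Knots have uniform priors over the square; a configurable number
of knots smaller than \(K\) is shared across sticks round-robin.

A geographically weighted observation-weight matrix is part of the model
family: with graph-step distances \(d_i(s)\) (shortest-path edge counts on
the contiguity graph; great-circle distances are the alternative metric), the
weight of area \(i\) at location \(s\) is 1 when \(d_i(s) \le 1\) and
\(\exp(-d_i(s)/b)\) otherwise, with \(b \sim \mathrm{Uniform}(0, D)\),
\(D = 100\). Unreachable pairs (areas in another graph component) get weight
zero, the limit of the decay at infinite distance.

### The two likelihood readings, and why `plain` is the default

The weight matrix admits two readings of the likelihood, and the package
implements both:

* **`plain`** — one Gaussian term per area. Because the focal self-weight is
  identically 1 under the weight rule, this is the literal single-likelihood
  reading; the spatial structure acts through the stick-breaking prior.
* **`composite`** — the geographically weighted *local* likelihood of the
  BGWR tradition: location \(s_i\) contributes the weighted density of
  *every* observation, \(\sum_j \tfrac12 \log \tfrac{W_j(s_i)}{2\pi\sigma^2(s_i)}
  - \tfrac{W_j(s_i)}{2\sigma^2(s_i)} r_j^2\). This is a pseudo-likelihood:
  each observation is reused at every location.

`plain` is the default because the composite pseudo-posterior with a
*sampled* bandwidth is empirically degenerate. The bandwidth's conditional
contains the normalizer \(\tfrac12 \sum \log W_{ij}(b)\), which grows
monotonically with \(b\); the per-location variances then inflate to absorb
the globally pooled residuals, which in turn flattens the penalty term, and
the chain settles at \(b\) near its upper bound with essentially equal
weights everywhere. At that point every cluster's coefficient conditional
pools all areas and the atoms collapse onto the global weighted
least-squares fit — clusters in name only. Starting the chain in the local
small-\(b\) regime does not help: the gradient of the pseudo-posterior
carries it back. The composite mode remains available (and is exercised by
the unit tests) for sensitivity analysis, and the fitted mode is recorded in
the run metadata, but it should be used with a fixed, externally chosen
bandwidth rather than a sampled one.

### Variance structure

With one observation per area, a free per-area \(\sigma^2(s_i)\) in plain
mode is nearly unidentified: its conditional is
\(\mathrm{InvGamma}(\alpha_1 + \tfrac12,\ \alpha_2 + r_i^2/2)\), which under
the diffuse default \(\alpha_1 = \alpha_2 = 0.1\) is extremely heavy-tailed.
In practice this turns the mixture into an overly robust one — any area can
absorb an arbitrarily bad fit by inflating its own variance — and the
partition fragments. The default therefore ties the variance to the cluster,
\(\sigma^2(s) = \sigma^2_{z(s)}\): the field still varies over space (through
the labels), every variance is informed by a whole cluster of observations,
and the inverse-gamma prior is shared. `sigma_structure = "area"` and
`"shared"` implement the alternatives.

### The base measure as the Occam guard

A Dirichlet-process mixture resists spurious clusters only through the prior
cost of occupying a new atom: the prior-predictive density that a freshly
used \(\beta_k\) must pay. With a tight base measure (scale matrix near the
identity) that cost is negligible against the likelihood gain of fitting
\(p = 6\) coefficients to a handful of self-selected areas, and small junk
clusters of 2–8 areas survive indefinitely. The default scale is therefore
deliberately diffuse, \(D_0 = 100 I\) (prior coefficient scale of order 10):
occupied atoms pay a real penalty, well-populated clusters are unaffected
(their likelihood dominates), and the posterior number of occupied clusters
concentrates near the number of genuine regions. This is the standard
diffuse-base-measure recommendation for DP mixtures, and the single most
consequential hyperparameter in the model.

### Kernel scale

\(\lambda\) defaults to 1 on the unit square. The intent is that one stick
can span one macro-region: with the squared-exponential kernel the fixed
bandwidth is then \(\lambda^2/2 = 0.5\), about the diameter of one of a
handful of compact regions. Much smaller kernels cannot cover a region, so
the prior forces each region across several sticks and the partition turns
into a kernel-footprint patchwork; much larger kernels stop discriminating
between regions at all. Both failure modes are easy to reproduce by setting
`lambda` to 0.25 or 4.

## Inference

A blocked Gibbs / Metropolis–Hastings sampler sweeps, in order:

1. **Assignments** — each \(z_i\) from its categorical conditional
   \(\propto p_k(s_i) \exp\{\ell_i(k)\}\), sampled jointly for all areas in
   log space by the Gumbel-max trick (max-subtraction underflow safety; the
   contract is never-NaN). With cluster-tied variances the Gaussian
   log-normalizer differs across candidate labels and is kept.
2. **Regression blocks** — \(\beta_k\) from its multivariate-normal
   conditional (precision \(X^\top A X + \Sigma_k^{-1}\), with \(A\)
   accumulating weight/variance over the cluster's areas); \((\mu_k,
   \Sigma_k)\) from the conjugate normal–inverse-Wishart refresh treating
   \(\beta_k\) as one observation; variances from their inverse-gamma
   conditionals. Empty clusters draw their atom from the current base
   measure, which is what lets new clusters be born.
3. **Stick blocks** — each \(V_k\) by *independence* MH proposed from the
   \(\mathrm{Beta}(a_v + n_k,\ b_v + n_{>k})\) conditional that would hold
   with flat kernels, corrected for the kernel factors; knots by random walk
   mixed with occasional independence draws from their uniform prior (so a
   kernel can jump between distant regions); random bandwidths by log-scale
   random walk; the GWR bandwidth \(b\) by random walk on \((0, D)\), which
   in plain mode simply samples its flat prior.
4. **Split–merge** — one Metropolized merge (all members of one occupied
   stick moved to another) or split (restricted-Gibbs reassignment of one
   stick's members onto an empty stick), in the spirit of Jain & Neal. The
   single-site sweep cannot dissolve two sticks sharing one effective atom,
   because that requires a coordinated block move; this move restores that
   mixing and is what lets the occupied-cluster count equilibrate.

Random-walk proposal scales adapt during burn-in only (Robbins–Monro toward
0.3 acceptance) and are frozen afterwards, keeping the retained chain
Markovian. All randomness flows from the single chain seed; equal seeds give
bit-identical draw archives.

**Initialization.** Labels warm-start from \(k\)-means (3 groups) on
per-area ridge-regularized local WLS coefficients, computed with genuinely
local weights (bandwidth of one third the median inter-area distance — flat
weights would make every local fit identical and the grouping meaningless),
then polished by a few hard-EM rounds on the actual regression objective,
which matters when neighbourhoods are small relative to \(p\). The first
knots start at the warm groups' centroids and their sticks at fraction 0.7,
so region-scale sticks exist from sweep one. Variances start at the
warm-start residual scale rather than at a prior draw or a fixed constant:
an inverse-gamma prior draw can start the chain at absurd scales, and a
fixed unit start washes out a sharp warm start whenever the true noise is
small. Everything else draws from its prior. The warm start is
seed-controlled and affects only the transient.

**Defaults.** \(m = 0\), \(D_0 = 100I\), \(c_0 = p + 2\),
\(a_v = b_v = 1\), \(\alpha_1 = \alpha_2 = 0.1\), \(D = 100\), truncation
\(K = 20\), knots \(= K\) unless set (the sensitivity studies use 9), no
intercept (matching the convention of fitting log-scaled data without one;
a flag adds it). Chains default to 10000 sweeps with 2000 burn-in — 8000
retained draws.

## Summaries

Point cluster configurations come from the label draws in two ways:
**Dahl's method** (the draw whose co-clustering membership matrix is closest
in least squares to the posterior mean membership matrix; ties to the
earliest draw) and the **posterior mode** (per-draw greedy label alignment
to the Dahl reference via the confusion matrix, then a per-area majority
vote, ties to the smaller label). Label switching is deliberately left free
during sampling — both summaries are invariant to it — and resolved only
here.

`cluster_table()` reports, per cluster and covariate, the posterior mean and
95% highest-posterior-density interval of the *aligned atom*: each retained
draw is aligned to the solution labels and the atom with the best membership
overlap contributes its coefficient draw. Averaging over member areas
instead would blend misassigned areas' atoms into every estimate. HPD
intervals are the shortest contiguous window of the sorted sample containing
\(\lceil \text{level} \cdot M \rceil\) points, earliest start on ties.

Model comparison uses WAIC in the variance-penalized form,
\(\mathrm{lppd} = \sum_i \log \tfrac1M \sum_d e^{\ell_{di}}\),
\(p_{\mathrm{waic}} = \sum_i \mathrm{Var}_d(\ell_{di})\),
\(\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{waic}})\), computed in log
space. The pointwise contributions are always the plain one-term-per-area
densities regardless of the fitting mode, so models are compared on the same
data partition. Clustering accuracy against known labels uses the Rand
index; replicate studies aggregate mean absolute bias, mean replicate
standard deviation (divisor \(R - 1\)) and mean squared error of the
per-area posterior coefficient estimates.

## The synthetic generator

`simulate_dataset()` generates the package's reference study conditions: 159
areas on a jittered rectangular lattice with rook contiguity, rescaled so
the largest centroid distance is 10; a fixed three-region partition of sizes
51/49/59 set by coordinate thresholds (a top slab plus a left/right split of
the remainder — compact blocks, because the regions this emulates are
compact and isotropic fixed-bandwidth kernels cannot express high-aspect
strips); six covariates drawn from independent zero-mean Gaussian processes
over the centroids with exponential covariance \(\exp(-\lVert s_i - s_j
\rVert / \phi)\), \(\phi = 0.9\); cluster-constant true coefficients
(defaulting to the three well-separated reference vectors returned by
`default_cluster_coefficients()`); and independent Gaussian noise.

The noise standard deviation defaults to **0.5**. This is a calibration, not
a free dial: the reference posterior intervals these conditions reproduce
have widths around 0.26 for clusters of roughly 50 areas, which implies a
residual standard deviation near \(0.26\sqrt{50}/3.92 \approx 0.47\); and a
direct Bayes-oracle computation (assign each area by likelihood under the
true atoms) shows that at noise 1 the attainable Rand index is capped near
0.70, inconsistent with the clustering accuracies these conditions are known
to produce. Both calculations are reproducible from the package alone.

What the generator does *not* emulate: irregular polygon geometries and
heterogeneous neighbour counts, covariate cross-correlation, non-Gaussian
errors, and missingness. Passing tests on this generator therefore show that
the method recovers compact, cluster-constant coefficient structure under
spatially correlated covariates — not that it is robust to real-map
irregularity or model misspecification.

## Problem sizes used in the shipped checks

The packaged test suite and the acceptance script run the full 159-area
generator with 2000-sweep / 500 burn-in chains (about 15–20 s per fit) and
10-replicate studies per kernel configuration; unit-level chains use 25–36
areas and a few hundred sweeps. These sizes give Monte-Carlo error around
±0.02 on a 10-replicate mean Rand index, which is the resolution at which
the reference values are quoted.

## Known limitations

* The composite likelihood with a sampled bandwidth is degenerate (above);
  treat `likelihood_mode = "composite"` as a fixed-bandwidth tool.
* The posterior number of occupied clusters in truncated DP mixtures is not
  a consistent estimator of the number of true groups; the Dahl and mode
  configurations are point summaries, and occasional extra small clusters
  in individual draws are expected.
* Conditional (stick-representation) samplers mix slowly across partition
  modes even with the split–merge move; multimodality on hard datasets is
  best diagnosed by comparing seeds.
* Great-circle distances assume (lon, lat) centroids; the synthetic lattice
  uses planar coordinates under the same column names and documents it.
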