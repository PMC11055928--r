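#' Model configuration
#'
#' Hyperparameters and structural choices of the clustered geographically
#' weighted regression. Cluster atoms `beta_k ~ N_p(mu_k, Sigma_k)` with a
#' conjugate normal-inverse-Wishart base measure
#' (`mu_k | Sigma_k ~ N_p(m, Sigma_k)`, `Sigma_k ~ IW(D0, c0)`), per-area
#' variances `sigma^2(s) ~ InvGamma(alpha1, alpha2)`, stick fractions
#' `V_k ~ Beta(a, b)` and a global GWR bandwidth `b ~ Uniform(0, D)`.
#'
#' Two likelihood readings are supported. `"plain"` (the default) keeps
#' one Gaussian term per area (the focal weight is identically 1 under the
#' weight rule), giving a Dirichlet-process mixture of regressions whose
#' spatial structure enters through the stick-breaking prior.
#' `"composite"` is the geographically weighted local pseudo-likelihood of
#' the BGWR tradition: the contribution of location `s_i` is the weighted
#' Gaussian density of *all* observations with weights `W_j(s_i)`. With a
#' sampled bandwidth the composite pseudo-posterior drifts to a degenerate
#' near-global regime (flat weights, inflated variances, clusters collapse
#' to a single global fit), so it is provided for completeness and
#' sensitivity analysis rather than as the default; the methods vignette
#' discusses this in detail.
#'
#' @param prior_mean Prior mean `m` of the cluster means (length `p`;
#'   `NULL` = zeros).
#' @param prior_scale Inverse-Wishart scale matrix `D0` of the cluster
#'   spreads (`NULL` = `100 * identity`). A deliberately diffuse base
#'   measure: the prior-predictive density an occupied atom must pay acts
#'   as the Occam penalty that guards a Dirichlet-process mixture against
#'   spurious small clusters, and a diffuse scale makes that penalty real
#'   while remaining negligible for well-populated clusters.
#' @param prior_df Inverse-Wishart degrees of freedom `c0` (`NULL` = `p + 2`;
#'   must exceed `p - 1`).
#' @param var_shape,var_rate Inverse-gamma parameters `alpha1`, `alpha2` of
#'   the per-area variances.
#' @param bandwidth_max Upper bound `D` of the uniform bandwidth prior.
#' @param likelihood_mode `"composite"` or `"plain"` (see Details).
#' @param sigma_structure How the variance field `sigma^2(s)` varies:
#'   `"cluster"` (default) ties it to the cluster membership, so it varies
#'   over space through `z(s)` while remaining identified with one
#'   observation per area; `"area"` gives every area its own variance;
#'   `"shared"` uses a single global variance. All three share the same
#'   inverse-gamma prior.
#' @param intercept Add an intercept column to the design (default off).
#' @param distance Distance metric feeding the GWR weights: shortest-path
#'   `"graph"` steps (default) or `"great_circle"`.
#' @param threshold Distance at or below which the GWR weight is exactly 1;
#'   `NULL` picks 1 for graph distance and 0 for great-circle distance.
#' @param stick A [stick_config()].
#' @return A list of class `sdp_gwr_config`.
#' @export
sdp_gwr_config <- function(prior_mean = NULL, prior_scale = NULL, prior_df = NULL,
                           var_shape = 0.1, var_rate = 0.1,
                           bandwidth_max = 100,
                           likelihood_mode = c("plain", "composite"),
                           sigma_structure = c("cluster", "area", "shared"),
                           intercept = FALSE,
                           distance = c("graph", "great_circle"),
                           threshold = NULL,
                           stick = stick_config()) {
  likelihood_mode <- match.arg(likelihood_mode)
  sigma_structure <- match.arg(sigma_structure)
  distance <- match.arg(distance)
  stopifnot(var_shape > 0, var_rate > 0, bandwidth_max > 0)
  if (!inherits(stick, "stick_config")) abort("`stick` must be a stick_config()")
  structure(list(prior_mean = prior_mean, prior_scale = prior_scale,
                 prior_df = prior_df,
                 var_shape = var_shape, var_rate = var_rate,
                 bandwidth_max = bandwidth_max,
                 likelihood_mode = likelihood_mode,
                 sigma_structure = sigma_structure,
                 intercept = intercept,
                 distance = distance,
                 threshold = threshold %||% if (distance == "graph") 1 else 0,
                 stick = stick),
            class = "sdp_gwr_config")
}

# resolve prior pieces that depend on the design dimension p
.resolve_priors <- function(config, p) {
  m <- config$prior_mean %||% rep(0, p)
  D0 <- config$prior_scale %||% diag(100, p)
  c0 <- config$prior_df %||% (p + 2)
  if (length(m) != p) abort("prior_mean has wrong length")
  if (!all(dim(D0) == c(p, p))) abort("prior_scale has wrong dimension")
  if (c0 <= p - 1) abort("prior_df must exceed p - 1")
  if (inherits(try(chol(D0), silent = TRUE), "try-error")) {
    abort("prior_scale must be positive definite")
  }
  list(m = m, D0 = D0, c0 = c0)
}

#' Per-area log-likelihood contribution
#'
#' The contribution of location `s_i` to the model log-likelihood. In
#' `"composite"` mode it is the geographically weighted local likelihood
#' at `s_i`: the sum over all areas `j` with positive weight of the
#' Gaussian log density of `y_j` with mean `x_j' beta_{z_i}` and variance
#' `sigma^2(s_i) / W_j(s_i)`. In `"plain"` mode only the focal term
#' `j = i` (weight 1) is kept.
#'
#' @param i Area index.
#' @param state Model state: a list with `z` (labels), `beta` (`K x p`
#'   coefficient matrix) and `sigma2` (length-`n` variances).
#' @param y Response vector.
#' @param X Design matrix (`n x p`).
#' @param weights GWR weight matrix from [gwr_weights()] (row `i` is
#'   `W(s_i)`); ignored in plain mode.
#' @param mode `"composite"` or `"plain"`.
#' @return A scalar log-likelihood contribution.
#' @export
area_loglik <- function(i, state, y, X, weights = NULL,
                        mode = c("composite", "plain")) {
  mode <- match.arg(mode)
  s2 <- state$sigma2[i]
  if (s2 <= 0) abort("zero variance in state")
  beta <- state$beta[state$z[i], ]
  r2 <- (y - drop(X %*% beta))^2
  if (mode == "plain") {
    dnorm(y[i], drop(X[i, , drop = FALSE] %*% beta), sqrt(s2), log = TRUE)
  } else {
    w <- weights[i, ]
    pos <- w > 0
    sum(0.5 * log(w[pos] / (2 * pi * s2)) - w[pos] * r2[pos] / (2 * s2))
  }
}

#' Pointwise log-likelihood vector
#'
#' One plain-mode (one term per observation) Gaussian log density per area,
#' `log N(y_i; x_i' beta_{z_i}, sigma^2(s_i))`. This is the partition of the
#' data log-likelihood used by [waic()], independent of the fitting mode.
#'
#' @inheritParams area_loglik
#' @return A length-`n` numeric vector that sums to the total plain-mode
#'   log-likelihood.
#' @export
pointwise_loglik <- function(state, y, X) {
  mu <- rowSums(X * state$beta[state$z, , drop = FALSE])
  dnorm(y, mu, sqrt(state$sigma2), log = TRUE)
}

#' Log prior density of a model state
#'
#' Sum of the log densities of every parameter block under the hierarchical
#' prior: `b ~ Uniform(0, D)`, `beta_k ~ N_p(mu_k, Sigma_k)`,
#' `mu_k | Sigma_k ~ N_p(m, Sigma_k)`, `Sigma_k ~ IW(D0, c0)`,
#' `sigma^2(s) ~ InvGamma(alpha1, alpha2)`, `V_k ~ Beta(a, b)` for `k < K`,
#' knots uniform on the unit square, and the configured bandwidth model for
#' `eps`. States outside the support return `-Inf`.
#'
#' @param state A list with `b`, `beta` (`K x p`), `mu` (`K x p`), `Sigma`
#'   (`p x p x K`), `sigma2`, `V`, `psi`, `eps`.
#' @param config An [sdp_gwr_config()].
#' @param p Number of covariates (defaults to `ncol(state$beta)`).
#' @return Scalar log prior density (`-Inf` outside the support).
#' @export
log_prior <- function(state, config, p = ncol(state$beta)) {
  pr <- .resolve_priors(config, p)
  sc <- config$stick
  K <- nrow(state$beta)
  if (state$b <= 0 || state$b >= config$bandwidth_max) return(-Inf)
  if (any(state$sigma2 <= 0)) return(-Inf)
  Vint <- state$V[seq_len(K - 1)]
  if (K > 1 && any(Vint <= 0 | Vint >= 1)) return(-Inf)
  if (any(state$psi < 0 | state$psi > 1)) return(-Inf)
  if (any(state$eps <= 0)) return(-Inf)
  lp <- -log(config$bandwidth_max)                       # b ~ U(0, D)
  for (k in seq_len(K)) {
    Sig <- as.matrix(state$Sigma[, , k])
    ld <- .ldet_pd(Sig)
    if (!is.finite(ld)) return(-Inf)
    lp <- lp + .dmvnorm_log(state$beta[k, ], state$mu[k, ], Sig, ld) +
      .dmvnorm_log(state$mu[k, ], pr$m, Sig, ld) +
      .dinvwishart_log(Sig, pr$D0, pr$c0, ld)
  }
  lp <- lp + sum(.dinvgamma(state$sigma2, config$var_shape, config$var_rate,
                            log = TRUE))
  if (K > 1) lp <- lp + sum(dbeta(Vint, sc$beta_a, sc$beta_b, log = TRUE))
  lp + .eps_log_prior(state$eps, sc)                     # knots: log 1 = 0
}

# ---- small multivariate density helpers (shared by prior and tests) ----

.ldet_pd <- function(S) {
  ch <- try(chol(S), silent = TRUE)
  if (inherits(ch, "try-error")) return(NA_real_)
  2 * sum(log(diag(ch)))
}

.dmvnorm_log <- function(x, mean, Sigma, ldet = .ldet_pd(Sigma)) {
  p <- length(x)
  q <- drop(crossprod(x - mean, solve(Sigma, x - mean)))
  -0.5 * (p * log(2 * pi) + ldet + q)
}

.lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

.dinvwishart_log <- function(S, D0, c0, ldet = .ldet_pd(S)) {
  p <- ncol(S)
  0.5 * c0 * .ldet_pd(D0) - 0.5 * c0 * p * log(2) - .lmvgamma(c0 / 2, p) -
    0.5 * (c0 + p + 1) * ldet - 0.5 * sum(diag(solve(S, D0)))
}
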