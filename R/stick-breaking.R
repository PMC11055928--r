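#' Spatial stick-breaking configuration
#'
#' Settings for the truncated spatial stick-breaking construction that
#' defines the location-specific Dirichlet-process weights. Each stick `k`
#' carries a Beta stick fraction `V_k`, a kernel centred at a knot
#' `psi` with bandwidths `eps = (eps1, eps2)`, and the location-specific
#' fraction is `V_k(s) = l_k(s) V_k` with `l_k(s)` the kernel value.
#'
#' Coordinates are affinely rescaled to the unit square before kernel
#' evaluation, so `lambda` (default 0.5) is on that scale. The four
#' bandwidth models are: `"fixed_lambda"` (`eps == lambda`), `"exp_lambda"`
#' (`eps ~ Exp` with mean `lambda`), `"fixed_lambda_sq_half"`
#' (`eps == lambda^2 / 2`) and `"inverse_gamma"`
#' (`eps ~ InvGamma(1.5, lambda^2 / 2)`). The first two are conventionally
#' paired with the uniform kernel, the last two with the squared
#' exponential.
#'
#' @param kernel Kernel family: `"squared_exponential"` or `"uniform"`.
#' @param bandwidth_prior One of `"fixed_lambda"`, `"exp_lambda"`,
#'   `"fixed_lambda_sq_half"`, `"inverse_gamma"`.
#' @param lambda Kernel scale hyperparameter on the unit-square scale
#'   (default 1, i.e. kernels of the order of the spatial domain, so a
#'   single stick can span one of a handful of macro-regions).
#' @param truncation Truncation level `K` of the stick-breaking mixture.
#' @param knots Number of distinct knots; when smaller than `truncation`
#'   sticks share knots round-robin. `NULL` means one knot per stick.
#' @param beta_a,beta_b Beta prior parameters of the stick fractions.
#' @return A list of class `stick_config`.
#' @export
stick_config <- function(kernel = c("squared_exponential", "uniform"),
                         bandwidth_prior = c("fixed_lambda_sq_half", "fixed_lambda",
                                             "exp_lambda", "inverse_gamma"),
                         lambda = 1,
                         truncation = 20,
                         knots = NULL,
                         beta_a = 1, beta_b = 1) {
  kernel <- match.arg(kernel)
  bandwidth_prior <- match.arg(bandwidth_prior)
  stopifnot(lambda > 0, truncation >= 1, beta_a > 0, beta_b > 0)
  knots <- knots %||% truncation
  stopifnot(knots >= 1, knots <= truncation)
  structure(list(kernel = kernel, bandwidth_prior = bandwidth_prior,
                 lambda = lambda, truncation = as.integer(truncation),
                 knots = as.integer(knots),
                 beta_a = beta_a, beta_b = beta_b),
            class = "stick_config")
}

# round-robin map from stick index to knot index
.knot_of <- function(K, J) ((seq_len(K) - 1L) %% J) + 1L

#' Evaluate a stick-breaking kernel
#'
#' Kernel value `l_k(s)` of a stick centred at knot `psi` with bandwidths
#' `eps`, at location `s` (both in the rescaled coordinate system). The
#' uniform kernel is the product over the two coordinates of
#' `1(|s_j - psi_j| < eps_j / 2)`; the squared exponential is the product
#' of `exp(-(s_j - psi_j)^2 / (2 eps_j^2))`.
#'
#' @param s Numeric length-2 location.
#' @param psi Numeric length-2 knot.
#' @param eps Positive length-2 (or scalar, recycled) bandwidths.
#' @param kind `"uniform"` or `"squared_exponential"`.
#' @return A scalar in `[0, 1]`.
#' @export
kernel_value <- function(s, psi, eps, kind = c("squared_exponential", "uniform")) {
  kind <- match.arg(kind)
  eps <- rep_len(eps, 2)
  if (any(eps <= 0)) abort("kernel bandwidths must be positive")
  d <- abs(s - psi)
  if (kind == "uniform") prod(as.numeric(d < eps / 2))
  else exp(-sum(d^2 / (2 * eps^2)))
}

# n x K kernel matrix over unit-square coordinates S (n x 2)
.kernel_matrix <- function(S, psi, eps, kind, knot_of) {
  K <- nrow(eps)
  L <- matrix(1, nrow(S), K)
  for (k in seq_len(K)) {
    d1 <- S[, 1] - psi[knot_of[k], 1]
    d2 <- S[, 2] - psi[knot_of[k], 2]
    L[, k] <- if (kind == "uniform") {
      (abs(d1) < eps[k, 1] / 2) * (abs(d2) < eps[k, 2] / 2)
    } else {
      exp(-d1^2 / (2 * eps[k, 1]^2) - d2^2 / (2 * eps[k, 2]^2))
    }
  }
  L
}

# location-wise stick-breaking probabilities from kernels and fractions;
# the final stick is forced to 1 so rows sum to 1 by construction
.stick_P <- function(L, V) {
  K <- length(V)
  Vs <- sweep(L, 2, V, `*`)
  Vs[, K] <- 1
  P <- Vs
  rem <- rep(1, nrow(L))
  for (k in seq_len(K)) {
    P[, k] <- Vs[, k] * rem
    rem <- rem * (1 - Vs[, k])
  }
  P
}

#' Location-specific stick-breaking weights
#'
#' Turns stick fractions and kernel values into the per-location cluster
#' probabilities `p_1(s), ..., p_K(s)`. The final stick fraction is forced
#' to one at every location, so the weights sum to one exactly.
#'
#' @param V Length-`K` stick fractions in `(0, 1)` (the last entry is
#'   ignored and treated as 1).
#' @param kernels An `n x K` matrix of kernel values `l_k(s)` in `[0, 1]`,
#'   or a length-`K` vector for a single location.
#' @return An `n x K` matrix (or vector) of probabilities; rows sum to 1.
#' @examples
#' stick_weights(c(0.3, 1), matrix(1, 1, 2))  # (0.3, 0.7)
#' @export
stick_weights <- function(V, kernels) {
  if (is.null(dim(kernels))) kernels <- matrix(kernels, nrow = 1)
  stopifnot(ncol(kernels) == length(V), all(kernels >= 0), all(kernels <= 1))
  P <- .stick_P(kernels, V)
  if (nrow(P) == 1) drop(P) else P
}

#' Draw the stick-breaking state from its prior
#'
#' Samples stick fractions `V_k ~ Beta(a, b)`, knots uniformly over the
#' unit square, and kernel bandwidths from the configured model.
#'
#' @param config A [stick_config()].
#' @return A list with `V` (length `K`, last entry 1), `psi` (`J x 2`
#'   knots), `eps` (`K x 2` bandwidths) and `knot_of` (stick-to-knot map).
#' @export
sample_stick_prior <- function(config) {
  stopifnot(inherits(config, "stick_config"))
  K <- config$truncation; J <- config$knots
  V <- rbeta(K, config$beta_a, config$beta_b)
  V[K] <- 1
  psi <- matrix(runif(J * 2), J, 2)
  eps <- .sample_eps_prior(K, config)
  list(V = V, psi = psi, eps = eps, knot_of = .knot_of(K, J))
}

.sample_eps_prior <- function(K, config) {
  lam <- config$lambda
  switch(config$bandwidth_prior,
    fixed_lambda = matrix(lam, K, 2),
    fixed_lambda_sq_half = matrix(lam^2 / 2, K, 2),
    exp_lambda = matrix(rexp(K * 2, rate = 1 / lam), K, 2),
    inverse_gamma = matrix(1 / rgamma(K * 2, shape = 1.5, rate = lam^2 / 2), K, 2),
    abort(sprintf("unknown bandwidth_prior '%s'", config$bandwidth_prior)))
}

# log prior density of the bandwidths under the configured model
.eps_log_prior <- function(eps, config) {
  lam <- config$lambda
  switch(config$bandwidth_prior,
    fixed_lambda = 0,
    fixed_lambda_sq_half = 0,
    exp_lambda = sum(dexp(eps, rate = 1 / lam, log = TRUE)),
    inverse_gamma = sum(.dinvgamma(eps, 1.5, lam^2 / 2, log = TRUE)))
}

.eps_is_random <- function(config) {
  config$bandwidth_prior %in% c("exp_lambda", "inverse_gamma")
}

.dinvgamma <- function(x, shape, rate, log = FALSE) {
  ld <- shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

# affine rescale of centroids to the unit square (degenerate dims -> 0.5)
.unit_coords <- function(lon, lat) {
  sc <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  }
  cbind(sc(lon), sc(lat))
}
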