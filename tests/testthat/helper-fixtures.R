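# shared fixtures: tiny graphs built in code, plus one cached default-size
# fit reused by the acceptance-level checks (computing it once keeps the
# suite fast without weakening any assertion)

.fixture_env <- new.env(parent = emptyenv())

chain_graph <- function(ids = c("a", "b", "c")) {
  n <- length(ids)
  area_graph(
    tibble::tibble(area_id = ids, lon = seq_len(n), lat = rep(0, n)),
    data.frame(from = ids[-n], to = ids[-1]))
}

# a small clustered dataset for smoke-level fitting tests
small_sim <- function(seed = 42, n = 36, partition = c(12, 11, 13)) {
  simulate_dataset(n = n, partition = partition, seed = seed)
}

# the study-condition fit: default generator, squared-exponential kernel
# with fixed lambda^2/2 bandwidth, 9 knots, truncation 20, reduced chain
default_study_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  s <- simulate_dataset(seed = 1)
  fit <- sdp_gwr(
    s$data, s$graph,
    sdp_gwr_config(stick = stick_config(kernel = "squared_exponential",
                                        bandwidth_prior = "fixed_lambda_sq_half",
                                        knots = 9, truncation = 20)),
    chain_config(n_iter = 2000, burn_in = 500, seed = 2))
  .fixture_env$sim <- s
  .fixture_env$fit <- fit
  fit
}

default_study_sim <- function() {
  default_study_fit()
  .fixture_env$sim
}

# minimal valid model state for prior/likelihood tests
toy_state <- function(K = 2, p = 1, n = 3, seed = 7) {
  set.seed(seed)
  list(z = rep_len(seq_len(K), n),
       beta = matrix(rnorm(K * p), K, p),
       mu = matrix(0, K, p),
       Sigma = array(diag(p), c(p, p, K)),
       sigma2 = rep(1, n),
       V = c(rep(0.5, K - 1), 1),
       psi = matrix(0.5, 1, 2),
       eps = matrix(0.5, K, 2),
       b = 1)
}
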