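test_that("coefficient full conditional equals the WLS-blend closed form", {
  set.seed(31)
  n <- 12; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  a <- runif(n, 0.2, 2)          # accumulated weight / variance per area
  Sigma <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  mu <- rnorm(p)
  fc <- sdpgwr:::.beta_conditional(X, y, a, solve(Sigma), mu)
  prec <- t(X) %*% diag(a) %*% X + solve(Sigma)
  expect_equal(fc$mean,
               drop(solve(prec, t(X) %*% diag(a) %*% y + solve(Sigma) %*% mu)),
               tolerance = 1e-10)

  # vague prior limit: the conditional mean approaches the WLS solution
  fc_vague <- sdpgwr:::.beta_conditional(X, y, a, diag(1e-10, p), rep(0, p))
  wls <- drop(solve(t(X) %*% diag(a) %*% X, t(X) %*% diag(a) %*% y))
  expect_equal(fc_vague$mean, wls, tolerance = 1e-6)

  # an area with weight zero has no influence
  a0 <- a; a0[4] <- 0
  y2 <- y; y2[4] <- 1e6
  fc1 <- sdpgwr:::.beta_conditional(X, y, a0, solve(Sigma), mu)
  fc2 <- sdpgwr:::.beta_conditional(X, y2, a0, solve(Sigma), mu)
  expect_equal(fc1$mean, fc2$mean)

  # scalar diagonal case: posterior mean lies between prior mean and WLS
  x1 <- matrix(1, 5, 1); y1 <- rep(2, 5)
  fcm <- sdpgwr:::.beta_conditional(x1, y1, rep(1, 5), matrix(1), 5)
  expect_true(fcm$mean > 2 && fcm$mean < 5)
})

test_that("assignment conditional matches exhaustive enumeration on a toy", {
  # n = 3, K = 2: compare against directly normalized p_k(s) * N(y; x'b_k, s2)
  set.seed(32)
  y <- c(0.4, -1.2, 2.2)
  X <- matrix(c(1, -0.8, 1.5), 3, 1)
  beta <- matrix(c(0.3, 1.4), 2, 1)
  sigma2 <- c(0.7, 1.1, 0.9)
  P <- rbind(c(0.6, 0.4), c(0.2, 0.8), c(0.5, 0.5))
  R2 <- (y - tcrossprod(X, beta))^2

  oracle <- t(sapply(1:3, function(i) {
    w <- P[i, ] * dnorm(y[i], X[i, ] * beta[, 1], sqrt(sigma2[i]))
    w / sum(w)
  }))
  lp <- sdpgwr:::.assign_logprobs(P, R2, NULL, sigma2, "plain")
  # the conditional omits k-free constants; normalize per row to compare
  got <- exp(lp - apply(lp, 1, max))
  got <- got / rowSums(got)
  expect_equal(got, oracle, tolerance = 1e-12)

  # empirical draw frequencies agree within 3 Monte-Carlo standard errors
  set.seed(33)
  R <- 40000
  draws <- matrix(0L, R, 3)
  for (r in seq_len(R)) draws[r, ] <- sdpgwr:::.sample_categorical_rows(lp)
  freq1 <- colMeans(draws == 1L)
  se <- sqrt(oracle[, 1] * (1 - oracle[, 1]) / R)
  expect_true(all(abs(freq1 - oracle[, 1]) < 3 * se + 1e-9))

  # equal likelihoods: conditional equals the stick prior weights
  lp_eq <- sdpgwr:::.assign_logprobs(P, matrix(1, 3, 2), NULL, sigma2, "plain")
  w_eq <- exp(lp_eq); w_eq <- w_eq / rowSums(w_eq)
  expect_equal(w_eq, P, tolerance = 1e-12)
})

test_that("stick-fraction MH recovers its Beta prior when the likelihood is off", {
  # zero areas: the z-likelihood term vanishes and the sampler should leave
  # the Beta(a, b) prior invariant
  set.seed(34)
  L <- matrix(numeric(0), 0, 3)
  P <- sdpgwr:::.stick_P(L, c(0.5, 0.5, 1))
  V <- c(0.5, 0.5, 1)
  draws <- numeric(4000)
  for (r in seq_along(draws)) {
    res <- sdpgwr:::.mh_V_step(1, V, L, P, integer(0), 2, 3)
    V <- res$V; P <- res$P
    draws[r] <- V[1]
  }
  expect_equal(mean(draws), 2 / 5, tolerance = 0.03)
  expect_true(all(draws > 0 & draws < 1))
})

test_that("MH proposals outside their support are always rejected", {
  set.seed(35)
  S <- matrix(runif(12), 6, 2)
  eps <- matrix(0.3, 2, 2)
  psi <- matrix(0.5, 2, 2)
  ko <- 1:2
  L <- sdpgwr:::.kernel_matrix(S, psi, eps, "squared_exponential", ko)
  V <- c(0.5, 1)
  P <- sdpgwr:::.stick_P(L, V)
  z <- rep(1L, 6)
  for (r in 1:300) {  # huge scale: most proposals leave the unit square
    res <- sdpgwr:::.mh_psi_step(1, psi, eps, V, L, P, z, S,
                                 "squared_exponential", ko, scale = 50,
                                 p_prior = 0)
    psi <- res$psi; L <- res$L; P <- res$P
    expect_true(all(psi >= 0 & psi <= 1))
  }
  b <- 50; W <- matrix(1, 2, 2)
  for (r in 1:200) {
    res <- sdpgwr:::.mh_b_step(b, W, matrix(0, 2, 2), 1, 0, matrix(0, 2, 2),
                               c(1L, 1L), c(1, 1), "plain", 100, scale = 500)
    b <- res$b
    expect_true(b > 0 && b < 100)
  }
})

test_that("split-merge move preserves a valid labelling and can merge duplicates", {
  # detailed balance: with fixed atoms the target over labellings is the
  # independent categorical field prop. to P * exp(llmat); on a 2-area,
  # 2-stick toy all four labellings are enumerable and the split-merge
  # kernel alone is ergodic over them, so its empirical distribution must
  # match the exact one
  set.seed(36)
  P <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  llmat <- rbind(c(0.2, -0.1), c(0, 0.4))
  states <- as.matrix(expand.grid(1:2, 1:2))
  w <- apply(states, 1, function(s) prod(P[cbind(1:2, s)] * exp(llmat[cbind(1:2, s)])))
  w <- w / sum(w)
  z <- c(1L, 1L)
  R <- 40000
  counts <- numeric(4)
  ok <- TRUE
  for (r in seq_len(R)) {
    z <- sdpgwr:::.mh_splitmerge_step(z, P, llmat)$z
    ok <- ok && all(z %in% 1:2)
    idx <- which(states[, 1] == z[1] & states[, 2] == z[2])
    counts[idx] <- counts[idx] + 1
  }
  expect_true(ok)
  freq <- counts / R
  # allow generous slack for the autocorrelation of the chain
  expect_true(all(abs(freq - w) < 6 * sqrt(w * (1 - w) / R) + 0.02))
})

test_that("a K = 1 chain reproduces the conjugate weighted-regression posterior", {
  set.seed(37)
  n <- 25
  X <- matrix(rnorm(n), n, 1)
  beta_true <- 1.5
  y <- drop(X * beta_true) + rnorm(n)
  g <- simulate_area_layout(n, c(8, 8, 9), seed = 5)$graph
  d <- tibble::tibble(area_id = g$areas$area_id, y = y, x1 = X[, 1],
                      lon = g$areas$lon, lat = g$areas$lat)
  S0 <- 0.25; c0 <- 500
  cfg <- sdp_gwr_config(likelihood_mode = "plain", sigma_structure = "shared",
                        prior_scale = matrix((c0 - 2) * S0), prior_df = c0,
                        var_shape = 1e5, var_rate = 1e5,   # pins sigma2 at 1
                        stick = stick_config(truncation = 1, knots = 1))
  fit <- sdp_gwr(d, g, cfg, chain_config(n_iter = 4000, burn_in = 500, seed = 38))
  # beta | mu ~ N(mu, S0), mu ~ N(0, S0)  =>  marginal prior N(0, 2 * S0)
  prec <- sum(X^2) + 1 / (2 * S0)
  post_mean <- sum(X * y) / prec
  expect_equal(mean(fit$draws$beta[, 1, 1]), post_mean, tolerance = 0.05)
  expect_equal(mean(fit$draws$sigma2), 1, tolerance = 0.02)
  expect_true(all(fit$draws$z == 1L))
})

test_that("chains are reproducible from their seed", {
  s <- small_sim()
  cfg <- sdp_gwr_config(stick = stick_config(truncation = 6, knots = 4))
  ch <- chain_config(n_iter = 80, burn_in = 20, thin = 3, seed = 99)
  f1 <- sdp_gwr(s$data, s$graph, cfg, ch)
  f2 <- sdp_gwr(s$data, s$graph, cfg, ch)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pointwise_loglik, f2$pointwise_loglik)
  expect_equal(nrow(f1$draws$z), (80 - 20) %/% 3)
  f3 <- sdp_gwr(s$data, s$graph, cfg, chain_config(n_iter = 80, burn_in = 20,
                                                   thin = 3, seed = 100))
  expect_false(identical(f1$draws$z, f3$draws$z))
})

test_that("default chain settings retain 8000 post-burn-in draws", {
  ch <- chain_config()
  keep <- seq(ch$burn_in + ch$thin, ch$n_iter, by = ch$thin)
  expect_length(keep, 8000)
})

test_that("adapted MH blocks land at moderate acceptance rates", {
  fit <- default_study_fit()
  expect_gt(fit$acceptance[["psi"]], 0.1)
  expect_lt(fit$acceptance[["psi"]], 0.6)
  expect_gt(fit$acceptance[["b"]], 0.1)
  expect_lt(fit$acceptance[["b"]], 0.6)
  # the Beta-conditional independence proposal should accept most moves
  expect_gt(fit$acceptance[["V"]], 0.5)
})
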