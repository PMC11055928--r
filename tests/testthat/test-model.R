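test_that("per-area log likelihood matches direct evaluation", {
  # n = 2 toy evaluated against a hand-summed weighted density
  y <- c(1.2, -0.4)
  X <- matrix(c(1, 0.5, -1, 2), 2, 2)
  st <- list(z = c(1L, 2L), beta = rbind(c(0.5, -0.2), c(1, 0.3)),
             sigma2 = c(0.8, 1.5))
  W <- rbind(c(1, 0.6), c(0.6, 1))

  mu1 <- drop(X %*% st$beta[1, ])
  oracle <- sum(dnorm(y, mu1, sqrt(st$sigma2[1] / W[1, ]), log = TRUE))
  expect_equal(area_loglik(1, st, y, X, W, mode = "composite"), oracle)

  # plain mode is the ordinary density of the focal observation
  expect_equal(area_loglik(2, st, y, X, mode = "plain"),
               dnorm(y[2], drop(X[2, ] %*% st$beta[2, ]), sqrt(1.5), log = TRUE))

  # composite with all weights 1 equals the unweighted sum over areas
  W1 <- matrix(1, 2, 2)
  expect_equal(area_loglik(1, st, y, X, W1, mode = "composite"),
               sum(dnorm(y, mu1, sqrt(st$sigma2[1]), log = TRUE)))

  # zero-weight areas drop out entirely
  W0 <- rbind(c(1, 0), c(0, 1))
  expect_equal(area_loglik(1, st, y, X, W0, mode = "composite"),
               dnorm(y[1], mu1[1], sqrt(st$sigma2[1]), log = TRUE))
})

test_that("pointwise log likelihood partitions the plain total", {
  set.seed(8)
  n <- 7; p <- 2
  X <- matrix(rnorm(n * p), n, p)
  st <- list(z = sample(1:2, n, replace = TRUE),
             beta = matrix(rnorm(4), 2, p), sigma2 = runif(n, 0.5, 2))
  y <- rnorm(n)
  pw <- pointwise_loglik(st, y, X)
  expect_length(pw, n)
  tot <- sum(vapply(seq_len(n), function(i) area_loglik(i, st, y, X, mode = "plain"),
                    numeric(1)))
  expect_equal(sum(pw), tot)

  # permuting area order permutes the vector
  perm <- sample(n)
  stp <- st; stp$z <- st$z[perm]; stp$sigma2 <- st$sigma2[perm]
  expect_equal(pointwise_loglik(stp, y[perm], X[perm, , drop = FALSE]), pw[perm])

  # single-area dataset gives a length-1 vector equal to area_loglik
  st1 <- list(z = 1L, beta = st$beta, sigma2 = st$sigma2[1])
  expect_equal(pointwise_loglik(st1, y[1], X[1, , drop = FALSE]),
               area_loglik(1, st1, y[1], X[1, , drop = FALSE], mode = "plain"))
})

test_that("log prior sums scalar densities and vanishes off support", {
  cfg <- sdp_gwr_config(prior_scale = diag(1), prior_df = 3,
                        stick = stick_config(truncation = 2, knots = 1,
                                             bandwidth_prior = "exp_lambda"))
  st <- toy_state(K = 2, p = 1)
  lp <- log_prior(st, cfg, p = 1)

  # 1-d oracle: every block reduces to a scalar density
  oracle <- -log(100) +                                        # b ~ U(0, 100)
    sum(dnorm(st$beta[, 1], st$mu[, 1], 1, log = TRUE)) +      # beta_k | mu, Sigma
    sum(dnorm(st$mu[, 1], 0, 1, log = TRUE)) +                 # mu_k | Sigma
    2 * sdpgwr:::.dinvgamma(1, 3 / 2, 1 / 2, log = TRUE) +     # IW(1, 3) on scalars
    sum(sdpgwr:::.dinvgamma(st$sigma2, 0.1, 0.1, log = TRUE)) +
    dbeta(0.5, 1, 1, log = TRUE) +                             # V_1 (V_2 forced)
    sum(dexp(st$eps, 1, log = TRUE))                           # eps ~ Exp(mean 1)
  expect_equal(lp, oracle)

  st_bad <- st; st_bad$b <- 200
  expect_equal(log_prior(st_bad, cfg, p = 1), -Inf)
  st_bad <- st; st_bad$sigma2[2] <- -1
  expect_equal(log_prior(st_bad, cfg, p = 1), -Inf)
  st_bad <- st; st_bad$psi[1, 1] <- 2
  expect_equal(log_prior(st_bad, cfg, p = 1), -Inf)

  # with fixed Sigma, varying beta alone shifts lp by the Normal kernel
  st2 <- st; st2$beta[1, 1] <- st$beta[1, 1] + 0.7
  expect_equal(log_prior(st2, cfg, p = 1) - lp,
               dnorm(st2$beta[1, 1], 0, 1, log = TRUE) -
                 dnorm(st$beta[1, 1], 0, 1, log = TRUE),
               tolerance = 1e-12)
})

test_that("posterior kernel is symmetric under cluster relabelling", {
  cfg <- sdp_gwr_config(stick = stick_config(truncation = 2, knots = 1))
  st <- toy_state(K = 2, p = 1)
  st$V <- c(0.5, 1)  # equal stick fractions so the label swap is exact
  y <- c(0.3, -0.2, 1.1); X <- matrix(c(1, -0.5, 2), 3, 1)
  swap <- function(s) {
    s2 <- s
    s2$beta <- s$beta[2:1, , drop = FALSE]
    s2$mu <- s$mu[2:1, , drop = FALSE]
    s2$Sigma <- s$Sigma[, , 2:1, drop = FALSE]
    s2$z <- 3L - s$z
    s2
  }
  ll <- function(s) sum(pointwise_loglik(s, y, X))
  st2 <- swap(st)
  expect_equal(ll(st) + log_prior(st, cfg, p = 1),
               ll(st2) + log_prior(st2, cfg, p = 1))
})

test_that("config constructors validate their inputs", {
  expect_error(sdp_gwr_config(var_shape = -1))
  expect_error(sdp_gwr_config(stick = list()), "stick_config")
  expect_error(stick_config(lambda = 0))
  expect_error(stick_config(knots = 30, truncation = 20))
  expect_error(chain_config(n_iter = 100, burn_in = 100))
  expect_error(sdpgwr:::.resolve_priors(sdp_gwr_config(prior_df = 2), p = 6),
               "exceed")
  cfg <- sdp_gwr_config(distance = "great_circle")
  expect_equal(cfg$threshold, 0)   # great-circle default: only self at weight 1
  expect_equal(sdp_gwr_config()$threshold, 1)
})
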