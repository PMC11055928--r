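test_that("membership matrices encode co-clustering", {
  expect_equal(membership_matrix(c(1, 1, 2)),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(membership_matrix(rep(4, 3)), matrix(1, 3, 3))
  z <- c(2, 1, 3, 1)
  expect_equal(membership_matrix(z), membership_matrix(c(7, 5, 9, 5)))
})

test_that("Dahl selection minimizes the least-squares criterion exactly", {
  draws <- rbind(c(1, 1, 2), c(1, 1, 2), c(1, 2, 2))
  sel <- dahl_select(draws)
  expect_equal(sel$index, 1)
  expect_equal(sel$labels, c(1L, 1L, 2L))

  # exhaustive-scan oracle on random draw sets
  set.seed(41)
  for (rep in 1:8) {
    zd <- matrix(sample(1:3, 10 * 6, replace = TRUE), 10, 6)
    sel <- dahl_select(zd)
    Bbar <- Reduce(`+`, lapply(seq_len(10), function(c)
      membership_matrix(zd[c, ]))) / 10
    dist <- sapply(seq_len(10), function(c)
      sum((membership_matrix(zd[c, ]) - Bbar)^2))
    expect_equal(sel$index, which.min(dist))
    expect_equal(sel$distance, dist, tolerance = 1e-10)
    expect_true(all(Bbar >= 0 & Bbar <= 1))
    expect_equal(Bbar, t(Bbar))
  }

  # invariant to per-draw label permutations
  zd <- rbind(c(1, 1, 2, 3), c(2, 2, 3, 1), c(1, 2, 2, 3))
  zd_perm <- rbind(c(3, 3, 1, 2), zd[2:3, ])
  expect_equal(dahl_select(zd)$index, dahl_select(zd_perm)$index)
  expect_equal(dahl_select(zd)$labels, dahl_select(zd_perm)$labels)

  expect_equal(dahl_select(rbind(c(2, 2, 1)))$index, 1)  # single draw
})

test_that("posterior-mode assignment aligns labels before voting", {
  # draws (1,2), (1,2), (2,1): the third is the same partition relabelled
  draws <- rbind(c(1L, 2L), c(1L, 2L), c(2L, 1L))
  expect_equal(mode_assignment(draws, reference = c(1L, 2L))$labels, c(1L, 2L))

  expect_equal(mode_assignment(rbind(c(2L, 2L, 1L)))$labels, c(1L, 1L, 2L))

  # global permutation of all draws changes nothing
  draws2 <- 3L - draws
  expect_equal(mode_assignment(draws)$labels, mode_assignment(draws2)$labels)
})

test_that("hpd intervals are shortest sorted windows with earliest-start ties", {
  expect_equal(hpd_interval(rep(3.2, 5)), c(lower = 3.2, upper = 3.2))
  expect_equal(hpd_interval(1:100, 0.95), c(lower = 1, upper = 95))
  expect_equal(hpd_interval(c(5, 1, 9), level = 1), c(lower = 1, upper = 9))
  expect_error(hpd_interval(numeric(0)), "empty")

  # a tight mode wins over a long tail
  x <- c(rnorm(200, 0, 0.1), 50, 60, 70, 80, 90, 100)
  h <- hpd_interval(x, 0.9)
  expect_lt(h[["upper"]], 1)

  # agrees with coda on a smooth unimodal sample
  set.seed(43)
  x <- rnorm(5000)
  h <- hpd_interval(x, 0.95)
  hc <- coda::HPDinterval(coda::as.mcmc(x), prob = 0.95)
  # coda uses a slightly different window count; agreement to ~2% suffices
  expect_equal(unname(h), unname(c(hc[1], hc[2])), tolerance = 0.02)
})

test_that("cluster labels and tables are consistent on a fitted model", {
  s <- small_sim()
  fit <- sdp_gwr(s$data, s$graph,
                 sdp_gwr_config(stick = stick_config(truncation = 8, knots = 4)),
                 chain_config(n_iter = 400, burn_in = 100, seed = 44))
  for (m in c("dahl", "mode")) {
    lab <- cluster_labels(fit, m)
    expect_equal(nrow(lab), fit$n)
    expect_equal(sort(unique(lab$cluster)), seq_len(max(lab$cluster)))
  }
  ct <- cluster_table(fit)
  lab <- cluster_labels(fit, "dahl")
  # sizes column sums to n within each term
  expect_equal(sum(ct$size[ct$term == "x1"]), fit$n)
  expect_equal(sort(unique(ct$cluster)), sort(unique(lab$cluster)))
  expect_true(all(ct$hpd_lower <= ct$estimate + 1e-9 | is.na(ct$estimate)))
  expect_true(all(ct$hpd_upper >= ct$estimate - 1e-9 | is.na(ct$estimate)))

  # tidy/glance accessors
  expect_equal(tidy(fit), ct)
  g <- glance(fit)
  expect_equal(g$n, fit$n)
  expect_equal(g$waic, waic(fit$pointwise_loglik)$waic)
})

test_that("a degenerate single-cluster draw set gives the global summary", {
  z <- matrix(1L, 50, 4)
  beta <- array(rnorm(50 * 2 * 1), c(50, 2, 1), dimnames = list(NULL, NULL, "x1"))
  fake <- structure(list(
    draws = list(z = z, beta = beta),
    n = 4L, p = 1L, K = 2L, covariates = "x1",
    area_ids = paste0("A", 1:4)), class = "sdp_gwr_fit")
  ct <- cluster_table(fake, labels = rep(1L, 4))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$estimate, mean(beta[, 1, 1]))
  h <- hpd_interval(beta[, 1, 1])
  expect_equal(ct$hpd_lower, h[["lower"]])
  expect_equal(ct$size, 4L)
})

test_that("well-separated synthetic clusters are recovered with faithful coefficients", {
  s <- small_sim(seed = 6)
  fit <- sdp_gwr(s$data, s$graph,
                 sdp_gwr_config(stick = stick_config(truncation = 8, knots = 4)),
                 chain_config(n_iter = 800, burn_in = 200, seed = 45))
  lab <- cluster_labels(fit, "dahl")
  # a 36-area lattice has a large boundary fraction; moderate agreement is
  # the realistic bar at this size
  expect_gte(rand_index(lab$cluster, s$truth$cluster), 0.6)
  ct <- cluster_table(fit)
  # every true cluster-1 coefficient should be inside the HPD of the
  # best-matching estimated cluster for most covariates
  x1 <- ct[ct$term == "x1", ]
  expect_lt(min(abs(x1$estimate - max(s$coefficients[, 1]))), 0.6)
})
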