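#' MCMC chain configuration
#'
#' @param n_iter Total number of sweeps (default 10000).
#' @param burn_in Discarded initial sweeps (default 2000; must be smaller
#'   than `n_iter`). With the defaults 8000 draws are retained.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed; every source of randomness in the run flows
#'   from it, so equal seeds give bit-identical draw archives.
#' @param adapt Adapt Metropolis-Hastings proposal scales during burn-in
#'   (Robbins-Monro toward `target_accept`); scales are frozen afterwards
#'   so the retained chain is Markovian.
#' @param target_accept Target acceptance rate for the adaptation.
#' @param verbose Emit a progress line every `progress_every` sweeps.
#' @param progress_every Sweeps between progress lines.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_iter = 10000, burn_in = 2000, thin = 1,
                         seed = NULL, adapt = TRUE, target_accept = 0.3,
                         verbose = FALSE, progress_every = 500) {
  stopifnot(burn_in < n_iter, thin >= 1, target_accept > 0, target_accept < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, adapt = adapt,
                 target_accept = target_accept, verbose = verbose,
                 progress_every = as.integer(progress_every)),
            class = "chain_config")
}

#' Fit the spatial Dirichlet process clustered GWR model
#'
#' Runs the blocked Gibbs / Metropolis-Hastings sampler over the full
#' hierarchical model: cluster assignments from their categorical full
#' conditionals, cluster coefficients and base-measure parameters from
#' conjugate normal / normal-inverse-Wishart updates, per-area variances
#' from inverse-gamma full conditionals, and stick fractions, knots, kernel
#' bandwidths and the GWR bandwidth by random-walk Metropolis steps. Sweep
#' order is assignments, regression blocks, stick blocks.
#'
#' @param data A data frame with columns `area_id`, response `y` and
#'   covariates (by default every column matching `x1, x2, ...`). Rows are
#'   matched to `graph` by `area_id`.
#' @param graph An [area_graph()] with one node per row of `data`.
#' @param config An [sdp_gwr_config()].
#' @param chain A [chain_config()].
#' @param covariates Optional character vector naming the covariate
#'   columns, in order.
#' @return An object of class `sdp_gwr_fit` with elements `draws` (retained
#'   draws of `z`, `beta`, `sigma2`, `b`, `V`), `pointwise_loglik`
#'   (draws x n matrix of plain per-area log densities), `acceptance`
#'   (per-block MH rates over the retained sweeps), the final `state`, and
#'   run metadata. Methods: [tidy()], [glance()], [cluster_labels()],
#'   [autoplot()].
#' @export
sdp_gwr <- function(data, graph, config = sdp_gwr_config(),
                    chain = chain_config(), covariates = NULL) {
  stopifnot(inherits(graph, "area_graph"), inherits(config, "sdp_gwr_config"),
            inherits(chain, "chain_config"))
  t0 <- proc.time()[["elapsed"]]
  data <- as_tibble(data)
  ids <- graph$areas$area_id
  if (!all(ids %in% data$area_id)) abort("data is missing rows for some graph areas")
  data <- data[match(ids, data$area_id), ]
  covariates <- covariates %||% .default_covariates(data)
  if (!length(covariates)) abort("no covariate columns found (expected x1, x2, ...)")
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  y <- as.numeric(data$y)
  if (anyNA(X) || anyNA(y)) abort("missing values in response or covariates")
  if (config$intercept) {
    X <- cbind(1, X); colnames(X)[1] <- "(Intercept)"
    covariates <- colnames(X)
  }
  n <- length(y); p <- ncol(X)
  pr <- .resolve_priors(config, p)
  sc <- config$stick
  K <- sc$truncation; J <- sc$knots
  knot_of <- .knot_of(K, J)
  mode <- config$likelihood_mode

  d <- switch(config$distance,
              graph = graph_distances(graph),
              great_circle = great_circle_distances(graph))
  thr <- config$threshold
  S <- .unit_coords(graph$areas$lon, graph$areas$lat)
  Dmax <- config$bandwidth_max
  reach <- is.finite(d)
  npos <- rowSums(reach)
  decay <- reach & d > thr
  sum_d_decay <- sum(d[decay])

  if (!is.null(chain$seed)) set.seed(chain$seed)

  # ---- initialization: warm-started labels, priors elsewhere ----
  # local ridge WLS needs genuinely local weights: decay over about a third
  # of the median inter-area distance, regardless of the bandwidth prior
  b0 <- max(median(d[is.finite(d) & d > 0]) / 3, thr, 1e-8)
  init_w <- gwr_weights(d, b0, thr)
  bhat <- .local_wls(X, y, init_w)
  n_groups <- min(3L, K, nrow(unique(bhat)))
  km <- tryCatch(kmeans(bhat, centers = n_groups, nstart = 10),
                 error = function(e) NULL)
  z <- if (is.null(km)) rep(1L, n) else as.integer(km$cluster)

  b <- runif(1, 0, Dmax)
  if (mode == "composite") {
    # the weighted likelihood for the bandwidth is bimodal: a local regime
    # (small b, per-area variances near the noise level) and a degenerate
    # near-global regime (flat weights, inflated variances); start in the
    # local regime and let the chain leave it if the data prefer otherwise
    b <- b0
  }
  st <- sample_stick_prior(sc)
  V <- st$V; psi <- st$psi; eps <- st$eps
  if (!is.null(km)) {
    # align the first knots with the warm-start groups so their sticks can
    # capture whole regions from the first sweeps
    for (k in seq_len(min(n_groups, J))) {
      psi[k, ] <- colMeans(S[z == k, , drop = FALSE])
    }
    V[seq_len(min(n_groups, K - 1L))] <- 0.7
  }
  Sigma <- array(0, c(p, p, K)); mu <- matrix(0, K, p); beta <- matrix(0, K, p)
  for (k in seq_len(K)) {
    Sigma[, , k] <- .rinvwishart(pr$c0, pr$D0)
    mu[k, ] <- .rmvnorm_cov(pr$m, Sigma[, , k])
    beta[k, ] <- .rmvnorm_cov(mu[k, ], Sigma[, , k])
  }
  if (!is.null(km)) {
    for (k in seq_len(n_groups)) beta[k, ] <- km$centers[k, ]
    # hard-EM polish of the warm start: the k-means features (local WLS
    # coefficients) are noisy when neighbourhoods are small relative to p,
    # but a few rounds of nearest-fit assignment + per-group refits on the
    # actual regression objective sharpen both labels and atoms
    RG <- 0.01 * diag(p)
    for (it in 1:5) {
      R2w <- (y - tcrossprod(X, beta[seq_len(n_groups), , drop = FALSE]))^2
      z <- max.col(-R2w, ties.method = "first")
      for (k in seq_len(n_groups)) {
        idx <- z == k
        if (any(idx)) {
          Xk <- X[idx, , drop = FALSE]
          beta[k, ] <- drop(solve(crossprod(Xk) + RG, crossprod(Xk, y[idx])))
        }
      }
    }
  }
  # start the variance field at the warm-start residual scale: a fixed unit
  # start would wash out a sharp warm start when the true noise is small
  r0 <- y - rowSums(X * beta[z, , drop = FALSE])
  s2g <- max(mean(r0^2), 1e-8)
  sstr <- config$sigma_structure
  s2k <- NULL
  if (sstr == "cluster") {
    s2k <- rep(s2g, K)
    for (k in unique(z)) s2k[k] <- max(mean(r0[z == k]^2), 1e-8)
    sigma2 <- s2k[z]
  } else {
    sigma2 <- rep(s2g, n)
  }

  W <- gwr_weights(d, b, thr)
  L <- .kernel_matrix(S, psi, eps, sc$kernel, knot_of)
  P <- .stick_P(L, V)

  # ---- storage ----
  keep <- seq(chain$burn_in + chain$thin, chain$n_iter, by = chain$thin)
  M <- length(keep)
  dr_z <- matrix(NA_integer_, M, n); dr_s2 <- matrix(NA_real_, M, n)
  dr_beta <- array(NA_real_, c(M, K, p)); dr_V <- matrix(NA_real_, M, K)
  dr_b <- numeric(M); dr_ll <- matrix(NA_real_, M, n)
  colnames(dr_z) <- ids; colnames(dr_s2) <- ids; colnames(dr_ll) <- ids
  dimnames(dr_beta) <- list(NULL, NULL, covariates)

  # MH proposal log-scales and bookkeeping
  ls <- list(V = rep(log(0.8), K), psi = rep(log(0.1), J),
             eps = rep(log(0.4), K), b = log(Dmax / 10))
  cnt <- list(V = rep(0, K), psi = rep(0, J), eps = rep(0, K), b = 0)
  acc_post <- c(V = 0, psi = 0, eps = 0, b = 0, sm = 0)
  try_post <- c(V = 0, psi = 0, eps = 0, b = 0, sm = 0)
  eps_random <- .eps_is_random(sc)
  adapting <- function(t) chain$adapt && t <= chain$burn_in

  m_idx <- 0L
  for (t in seq_len(chain$n_iter)) {
    post <- t > chain$burn_in
    # ---- cluster assignments ----
    R2 <- (y - tcrossprod(X, beta))^2
    lp <- .assign_logprobs(P, R2, W, sigma2, mode, s2k, npos)
    z <- .sample_categorical_rows(lp)
    if (sstr == "cluster") sigma2 <- s2k[z]

    # ---- regression blocks ----
    for (k in seq_len(K)) {
      idx <- which(z == k)
      if (length(idx)) {
        a <- if (mode == "composite") {
          colSums(W[idx, , drop = FALSE] / sigma2[idx])
        } else {
          av <- numeric(n); av[idx] <- 1 / sigma2[idx]; av
        }
        Sinv <- .solve_pd(Sigma[, , k])
        fc <- .beta_conditional(X, y, a, Sinv, mu[k, ])
        beta[k, ] <- .rmvnorm_prec(fc$mean, fc$chol_prec)
      } else {
        beta[k, ] <- .rmvnorm_cov(mu[k, ], Sigma[, , k])
      }
      bm <- .update_base_measure(beta[k, ], pr$m, pr$D0, pr$c0)
      mu[k, ] <- bm$mu; Sigma[, , k] <- bm$Sigma
    }
    R2 <- (y - tcrossprod(X, beta))^2
    R2z <- R2[cbind(seq_len(n), z)]
    qz <- if (mode == "composite") (W %*% R2)[cbind(seq_len(n), z)] else R2z
    ct <- if (mode == "composite") npos else rep(1, n)
    if (sstr == "area") {
      sigma2 <- 1 / rgamma(n, shape = config$var_shape + ct / 2,
                           rate = config$var_rate + qz / 2)
    } else if (sstr == "shared") {
      s2 <- 1 / rgamma(1, shape = config$var_shape + sum(ct) / 2,
                       rate = config$var_rate + sum(qz) / 2)
      sigma2 <- rep(s2, n)
    } else {
      for (k in seq_len(K)) {
        idx <- which(z == k)
        s2k[k] <- 1 / rgamma(1, shape = config$var_shape + sum(ct[idx]) / 2,
                             rate = config$var_rate + sum(qz[idx]) / 2)
      }
      sigma2 <- s2k[z]
    }

    # ---- stick blocks ----
    if (K > 1) {
      for (k in seq_len(K - 1L)) {
        res <- .mh_V_step(k, V, L, P, z, sc$beta_a, sc$beta_b)
        V <- res$V; P <- res$P
        if (post) { acc_post["V"] <- acc_post["V"] + res$accepted
                    try_post["V"] <- try_post["V"] + 1 }
      }
    }
    for (j in seq_len(J)) {
      res <- .mh_psi_step(j, psi, eps, V, L, P, z, S, sc$kernel, knot_of,
                          exp(ls$psi[j]))
      psi <- res$psi; L <- res$L; P <- res$P
      cnt$psi[j] <- cnt$psi[j] + 1
      if (adapting(t)) ls$psi[j] <- .rm_adapt(ls$psi[j], res$accepted,
                                              cnt$psi[j], chain$target_accept)
      if (post) { acc_post["psi"] <- acc_post["psi"] + res$accepted
                  try_post["psi"] <- try_post["psi"] + 1 }
    }
    if (eps_random) {
      for (k in seq_len(K)) {
        res <- .mh_eps_step(k, eps, psi, V, L, P, z, S, sc, knot_of,
                            exp(ls$eps[k]))
        eps <- res$eps; L <- res$L; P <- res$P
        cnt$eps[k] <- cnt$eps[k] + 1
        if (adapting(t)) ls$eps[k] <- .rm_adapt(ls$eps[k], res$accepted,
                                                cnt$eps[k], chain$target_accept)
        if (post) { acc_post["eps"] <- acc_post["eps"] + res$accepted
                    try_post["eps"] <- try_post["eps"] + 1 }
      }
    }
    # ---- split-merge moves on the assignments ----
    # several attempts per sweep: the per-stick likelihood matrix is fixed
    # during the block, so extra attempts cost almost nothing and let
    # redundant atoms dissolve within a single sweep
    llmat <- .loglik_matrix(R2, W, sigma2, mode, s2k, npos)
    for (att in 1:5) {
      res <- .mh_splitmerge_step(z, P, llmat)
      if (res$accepted) {
        z <- res$z
        if (sstr == "cluster") sigma2 <- s2k[z]
      }
      if (post) { acc_post["sm"] <- acc_post["sm"] + res$accepted
                  try_post["sm"] <- try_post["sm"] + 1 }
    }

    res <- .mh_b_step(b, W, d, thr, sum_d_decay, R2, z, sigma2, mode, Dmax,
                      exp(ls$b))
    b <- res$b; W <- res$W
    cnt$b <- cnt$b + 1
    if (adapting(t)) ls$b <- .rm_adapt(ls$b, res$accepted, cnt$b,
                                       chain$target_accept)
    if (post) { acc_post["b"] <- acc_post["b"] + res$accepted
                try_post["b"] <- try_post["b"] + 1 }

    # ---- retain ----
    if (post && (t - chain$burn_in) %% chain$thin == 0L) {
      m_idx <- m_idx + 1L
      dr_z[m_idx, ] <- z
      dr_beta[m_idx, , ] <- beta
      dr_s2[m_idx, ] <- sigma2
      dr_V[m_idx, ] <- V
      dr_b[m_idx] <- b
      dr_ll[m_idx, ] <- dnorm(y, rowSums(X * beta[z, , drop = FALSE]),
                              sqrt(sigma2), log = TRUE)
    }
    if (chain$verbose && t %% chain$progress_every == 0L) {
      message(sprintf("sweep %d/%d | occupied %d | b %.2f",
                      t, chain$n_iter, length(unique(z)), b))
    }
  }

  acceptance <- ifelse(try_post > 0, acc_post / try_post, NA_real_)
  structure(list(
    draws = list(z = dr_z, beta = dr_beta, sigma2 = dr_s2, V = dr_V, b = dr_b),
    pointwise_loglik = dr_ll,
    acceptance = acceptance,
    state = list(z = z, beta = beta, mu = mu, Sigma = Sigma, sigma2 = sigma2,
                 s2k = s2k, V = V, psi = psi, eps = eps, b = b),
    config = config, chain = chain,
    covariates = covariates, area_ids = ids, graph = graph,
    n = n, p = p, K = K,
    runtime = proc.time()[["elapsed"]] - t0
  ), class = "sdp_gwr_fit")
}

#' @export
print.sdp_gwr_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<sdp_gwr_fit> %d areas, %d covariates, %s likelihood\n",
                     "  %d retained draws; Dahl solution: %d clusters; WAIC %.1f\n"),
              x$n, x$p, x$config$likelihood_mode,
              nrow(x$draws$z), g$n_clusters, g$waic))
  invisible(x)
}

.default_covariates <- function(data) {
  nm <- grep("^x[0-9]+$", names(data), value = TRUE)
  nm[order(as.integer(sub("^x", "", nm)))]
}

# per-area ridge-regularized weighted least squares (warm start)
.local_wls <- function(X, y, W, ridge = 0.1) {
  n <- nrow(X); p <- ncol(X)
  out <- matrix(0, n, p)
  R <- ridge * diag(p)
  for (i in seq_len(n)) {
    w <- W[i, ]
    out[i, ] <- drop(solve(crossprod(X, X * w) + R, crossprod(X, w * y)))
  }
  out
}

# ---- full-conditional building blocks (unit-tested against oracles) ----

# per-area per-stick log likelihood terms (the label-dependent part); with
# cluster-level variances (s2k given) the variance depends on the candidate
# label, so the Gaussian log-normalizer no longer cancels across clusters
.loglik_matrix <- function(R2, W, sigma2, mode, s2k = NULL, npos = NULL) {
  if (is.null(s2k)) {
    if (mode == "composite") -(W %*% R2) / (2 * sigma2) else -R2 / (2 * sigma2)
  } else if (mode == "composite") {
    -sweep(W %*% R2, 2, 2 * s2k, `/`) - outer(npos / 2, log(s2k))
  } else {
    -sweep(R2, 2, 2 * s2k, `/`) -
      matrix(log(s2k) / 2, nrow(R2), length(s2k), byrow = TRUE)
  }
}

# unnormalized log conditional probabilities of the assignments
.assign_logprobs <- function(P, R2, W, sigma2, mode, s2k = NULL, npos = NULL) {
  log(P) + .loglik_matrix(R2, W, sigma2, mode, s2k, npos)
}

# one categorical draw per row of a matrix of unnormalized log masses
.sample_categorical_rows <- function(lp) {
  g <- -log(-log(matrix(runif(length(lp)), nrow(lp))))
  max.col(lp + g, ties.method = "first")
}

# Gaussian full conditional of a cluster coefficient vector:
# precision = X' diag(a) X + Sigma^{-1}, a = accumulated weight/variance
.beta_conditional <- function(X, y, a, Sigma_inv, mu) {
  prec <- crossprod(X, X * a) + Sigma_inv
  ch <- try(chol(prec), silent = TRUE)
  if (inherits(ch, "try-error")) {
    abort("singular precision in coefficient update (collinear design?)")
  }
  rhs <- crossprod(X, a * y) + Sigma_inv %*% mu
  mean <- backsolve(ch, forwardsolve(t(ch), rhs))
  list(mean = drop(mean), chol_prec = ch)
}

.rmvnorm_prec <- function(mean, chol_prec) {
  drop(mean + backsolve(chol_prec, rnorm(length(mean))))
}

.rmvnorm_cov <- function(mean, Sigma) {
  drop(mean + crossprod(chol(Sigma), rnorm(length(mean))))
}

.solve_pd <- function(S) chol2inv(chol(S))

.rinvwishart <- function(nu, S) {
  Wm <- rWishart(1, nu, .solve_pd(S))[, , 1]
  Si <- .solve_pd(Wm)
  (Si + t(Si)) / 2
}

# conjugate normal-inverse-Wishart refresh of one cluster's base measure,
# treating beta_k as a single observation with prior precision kappa0 = 1
.update_base_measure <- function(beta_k, m, D0, c0) {
  dv <- beta_k - m
  Sn <- D0 + 0.5 * tcrossprod(dv)
  Sigma <- .rinvwishart(c0 + 1, (Sn + t(Sn)) / 2)
  mu <- .rmvnorm_cov((m + beta_k) / 2, Sigma / 2)
  list(mu = mu, Sigma = Sigma)
}

# stick-assignment log likelihood: sum_i log p_{z_i}(s_i)
.sll <- function(P, z) {
  if (!length(z)) return(0)
  sum(log(P[cbind(seq_along(z), z)]))
}

# independence MH on one stick fraction, proposing from the Beta full
# conditional that would hold with flat kernels (l == 1) and correcting
# for the kernel factors; with wide kernels acceptance is near 1, which
# gives the rich-get-richer feedback needed to starve duplicated atoms
.mh_V_step <- function(k, V, L, P, z, beta_a, beta_b, scale = NULL) {
  vk <- V[k]
  n_k <- sum(z == k); n_gt <- sum(z > k)
  a_prop <- beta_a + n_k; b_prop <- beta_b + n_gt
  vn <- rbeta(1, a_prop, b_prop)
  if (vn <= 0 || vn >= 1) return(list(V = V, P = P, accepted = FALSE))
  Vn <- V; Vn[k] <- vn
  Pn <- .stick_P(L, Vn)
  logr <- dbeta(vn, beta_a, beta_b, log = TRUE) -
    dbeta(vk, beta_a, beta_b, log = TRUE) +
    .sll(Pn, z) - .sll(P, z) +
    dbeta(vk, a_prop, b_prop, log = TRUE) -
    dbeta(vn, a_prop, b_prop, log = TRUE)
  if (is.finite(logr) && log(runif(1)) < logr) {
    list(V = Vn, P = Pn, accepted = TRUE)
  } else list(V = V, P = P, accepted = FALSE)
}

# MH on one knot: random walk, mixed with occasional independence draws
# from the uniform prior so a kernel can jump between distant regions
# (both components are symmetric, so no proposal correction is needed)
.mh_psi_step <- function(j, psi, eps, V, L, P, z, S, kind, knot_of, scale,
                         p_prior = 0.2) {
  prop <- if (runif(1) < p_prior) runif(2) else psi[j, ] + rnorm(2) * scale
  if (any(prop < 0 | prop > 1)) {
    return(list(psi = psi, L = L, P = P, accepted = FALSE))
  }
  psin <- psi; psin[j, ] <- prop
  ks <- which(knot_of == j)
  Ln <- L
  Ln[, ks] <- .kernel_matrix(S, psin, eps[ks, , drop = FALSE], kind,
                             rep(j, length(ks)))[, seq_along(ks)]
  Pn <- .stick_P(Ln, V)
  logr <- .sll(Pn, z) - .sll(P, z)
  if (is.finite(logr) && log(runif(1)) < logr) {
    list(psi = psin, L = Ln, P = Pn, accepted = TRUE)
  } else list(psi = psi, L = L, P = P, accepted = FALSE)
}

# log-scale random-walk MH on one stick's kernel bandwidth pair
.mh_eps_step <- function(k, eps, psi, V, L, P, z, S, sc, knot_of, scale) {
  en <- eps[k, ] * exp(rnorm(2) * scale)
  epsn <- eps; epsn[k, ] <- en
  Ln <- L
  Ln[, k] <- .kernel_matrix(S, psi, epsn[k, , drop = FALSE], sc$kernel,
                            knot_of[k])[, 1]
  Pn <- .stick_P(Ln, V)
  logr <- .sll(Pn, z) - .sll(P, z) +
    .eps_log_prior(en, sc) - .eps_log_prior(eps[k, ], sc) +
    sum(log(en)) - sum(log(eps[k, ]))
  if (is.finite(logr) && log(runif(1)) < logr) {
    list(eps = epsn, L = Ln, P = Pn, accepted = TRUE)
  } else list(eps = eps, L = L, P = P, accepted = FALSE)
}

# Metropolized split-merge move on the cluster assignments (restricted-
# Gibbs proposal in the spirit of Jain & Neal). The single-site assignment
# sweep cannot dissolve two sticks that share essentially one atom, because
# that requires a coordinated move of a whole block of areas; proposing to
# merge one occupied stick into another (and, for reversibility, to split
# one stick onto an empty one by restricted Gibbs) restores that mixing.
# `llmat` holds per-area per-stick log likelihood terms, `P` the current
# stick probabilities; atoms themselves are left untouched.
.mh_splitmerge_step <- function(z, P, llmat) {
  K <- ncol(P)
  occ <- sort(unique(z))
  emp <- setdiff(seq_len(K), occ)
  lw <- log(P) + llmat
  no_move <- list(z = z, accepted = FALSE)
  if (runif(1) < 0.5) {                      # ---- merge k into j ----
    if (length(occ) < 2) return(no_move)
    pair <- sample(occ, 2)
    j <- pair[1]; k <- pair[2]
    mem <- which(z == k)
    zn <- z; zn[mem] <- j
    dtarget <- sum(lw[mem, j] - lw[mem, k])
    # reverse split: pick source j among occupied of zn, target k among its
    # empties, then reassign the merged block by restricted Gibbs
    occ_n <- length(unique(zn)); emp_n <- K - occ_n
    block <- which(zn == j)
    pk <- 1 / (1 + exp(lw[block, j] - lw[block, k]))   # P(side k)
    chose_k <- z[block] == k
    lq_split <- -log(occ_n) - log(emp_n) +
      sum(log(ifelse(chose_k, pk, 1 - pk)))
    lq_merge <- -log(length(occ) * (length(occ) - 1))  # ordered (j, k)
    la <- dtarget + lq_split - lq_merge
    if (is.finite(la) && log(runif(1)) < la) list(z = zn, accepted = TRUE)
    else no_move
  } else {                                   # ---- split j onto empty k ----
    if (!length(emp) || !length(occ)) return(no_move)
    j <- if (length(occ) == 1) occ else sample(occ, 1)
    k <- if (length(emp) == 1) emp else sample(emp, 1)
    block <- which(z == j)
    pk <- 1 / (1 + exp(lw[block, j] - lw[block, k]))
    side_k <- runif(length(block)) < pk
    if (!any(side_k) || all(side_k)) return(no_move)
    zn <- z; zn[block[side_k]] <- k
    dtarget <- sum(lw[block[side_k], k] - lw[block[side_k], j])
    lq_split <- -log(length(occ)) - log(length(emp)) +
      sum(log(ifelse(side_k, pk, 1 - pk)))
    occ_n <- length(occ) + 1
    lq_merge <- -log(occ_n * (occ_n - 1))              # ordered (j, k)
    la <- dtarget + lq_merge - lq_split
    if (is.finite(la) && log(runif(1)) < la) list(z = zn, accepted = TRUE)
    else no_move
  }
}

# random-walk MH on the GWR bandwidth b ~ Uniform(0, D); in composite mode
# the target is the full geographically weighted likelihood (both the
# 0.5*log W normalization and the weighted quadratic depend on b), in plain
# mode the likelihood is free of b and the move samples the flat prior
.mh_b_step <- function(b, W, d, thr, sum_d_decay, R2, z, sigma2, mode, Dmax,
                       scale) {
  prop <- b + rnorm(1) * scale
  if (prop <= 0 || prop >= Dmax) {
    return(list(b = b, W = W, accepted = FALSE))
  }
  if (mode == "plain") {
    return(list(b = prop, W = gwr_weights(d, prop, thr), accepted = TRUE))
  }
  n <- length(z)
  target <- function(bb, Wb) {
    -sum_d_decay / (2 * bb) -
      sum((Wb %*% R2)[cbind(seq_len(n), z)] / (2 * sigma2))
  }
  Wn <- gwr_weights(d, prop, thr)
  logr <- target(prop, Wn) - target(b, W)
  if (is.finite(logr) && log(runif(1)) < logr) {
    list(b = prop, W = Wn, accepted = TRUE)
  } else list(b = b, W = W, accepted = FALSE)
}

# Robbins-Monro log-scale adaptation toward a target acceptance rate
.rm_adapt <- function(log_scale, accepted, count, target) {
  log_scale + min(0.25, count^-0.6) * (as.numeric(accepted) - target)
}
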