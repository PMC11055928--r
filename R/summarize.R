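#' Pairwise co-clustering membership matrix
#'
#' Binary matrix with `B[i, j] = 1` when areas `i` and `j` share a label.
#'
#' @param z An integer (or factor/character) label vector.
#' @return An `n x n` symmetric 0/1 matrix with unit diagonal.
#' @export
membership_matrix <- function(z) {
  z <- as.integer(factor(z))
  outer(z, z, `==`) + 0
}

# mean co-clustering matrix over draws (rows of z_draws are draws)
.mean_membership <- function(z_draws) {
  M <- nrow(z_draws); n <- ncol(z_draws)
  B <- matrix(0, n, n)
  for (k in sort(unique(as.vector(z_draws)))) {
    Ik <- z_draws == k
    B <- B + crossprod(Ik)
  }
  B / M
}

#' Dahl's least-squares cluster configuration
#'
#' Selects the posterior draw whose membership matrix is closest, in the
#' elementwise least-squares sense, to the mean membership matrix over all
#' draws. Ties go to the earliest draw.
#'
#' @param z_draws A draws-by-areas integer matrix of label draws.
#' @return A list with `index` (selected draw), `labels` (its label vector
#'   relabelled to contiguous integers in order of first appearance),
#'   `distance` (the squared distances of every draw) and `mean_membership`.
#' @export
dahl_select <- function(z_draws) {
  z_draws <- rbind(z_draws)
  if (nrow(z_draws) < 1) abort("need at least one draw")
  Bbar <- .mean_membership(z_draws)
  A <- 1 - 2 * Bbar
  const <- sum(Bbar^2)
  dist <- vapply(seq_len(nrow(z_draws)), function(c) {
    zc <- z_draws[c, ]
    s <- 0
    for (k in unique(zc)) {
      idx <- which(zc == k)
      s <- s + sum(A[idx, idx])
    }
    s + const
  }, numeric(1))
  idx <- which.min(dist)
  list(index = idx, labels = .relabel(z_draws[idx, ]), distance = dist,
       mean_membership = Bbar)
}

# relabel to contiguous integers 1..G in order of first appearance
.relabel <- function(z) as.integer(factor(z, levels = unique(z)))

#' Posterior-mode cluster configuration
#'
#' Each draw is first relabelled to best agree with a reference labelling
#' (greedy matching on the confusion matrix, largest overlap first); each
#' area then takes its most frequent aligned label, ties going to the
#' smaller label.
#'
#' @param z_draws A draws-by-areas integer matrix of label draws.
#' @param reference Reference label vector for the alignment; defaults to
#'   the Dahl selection over the same draws.
#' @return A list with `labels` (length-n contiguous integer labels) and
#'   `reference`.
#' @export
mode_assignment <- function(z_draws, reference = NULL) {
  z_draws <- rbind(z_draws)
  reference <- reference %||% dahl_select(z_draws)$labels
  K <- max(max(z_draws), max(reference))
  n <- ncol(z_draws)
  counts <- matrix(0L, n, K)
  for (c in seq_len(nrow(z_draws))) {
    zc <- .align_labels(z_draws[c, ], reference, K)
    counts[cbind(seq_len(n), zc)] <- counts[cbind(seq_len(n), zc)] + 1L
  }
  list(labels = .relabel(max.col(counts, ties.method = "first")),
       reference = reference)
}

# greedy confusion-matrix matching of draw labels onto reference labels;
# returns map[draw_label] = reference label, 0 where a draw label has no
# overlap with any still-unclaimed reference label
.align_map <- function(z, ref, K) {
  cm <- matrix(0L, K, K)
  tab <- table(z, ref)
  cm[cbind(as.integer(rownames(tab))[row(tab)],
           as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  map <- integer(K)
  free_rows <- rep(TRUE, K); free_cols <- rep(TRUE, K)
  repeat {
    sub <- cm
    sub[!free_rows, ] <- -1L; sub[, !free_cols] <- -1L
    best <- which.max(sub)           # earliest index wins ties
    if (sub[best] <= 0L) break
    r <- (best - 1L) %% K + 1L; cc <- (best - 1L) %/% K + 1L
    map[r] <- cc
    free_rows[r] <- FALSE; free_cols[cc] <- FALSE
    if (!any(free_rows) || !any(free_cols)) break
  }
  map
}

.align_labels <- function(z, ref, K) {
  map <- .align_map(z, ref, K)
  left <- which(map == 0L)
  if (length(left)) map[left] <- setdiff(seq_len(K), map)[seq_along(left)]
  map[z]
}

#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted sample containing
#' `ceiling(level * M)` points; width ties go to the earliest start.
#'
#' @param samples Numeric vector of (at least 2) posterior draws.
#' @param level Coverage level in `(0, 1]`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(1:100, 0.95)   # (1, 95)
#' @export
hpd_interval <- function(samples, level = 0.95) {
  if (!length(samples)) abort("empty sample")
  if (level <= 0 || level > 1) abort("`level` must be in (0, 1]")
  xs <- sort(samples)
  M <- length(xs)
  m <- ceiling(level * M)
  if (m >= M) return(c(lower = xs[1], upper = xs[M]))
  starts <- seq_len(M - m + 1)
  widths <- xs[starts + m - 1] - xs[starts]
  s <- starts[which.min(widths)]
  c(lower = xs[s], upper = xs[s + m - 1])
}

#' Cluster labels from a fitted model
#'
#' Point estimate of the cluster configuration from the posterior label
#' draws, by Dahl's least-squares method or the posterior mode.
#'
#' @param fit An [sdp_gwr()] fit.
#' @param method `"dahl"` or `"mode"`.
#' @return A tibble with `area_id`, `cluster` (contiguous integers) and the
#'   chosen `method`; the underlying solution is attached as attribute
#'   `"solution"`.
#' @export
cluster_labels <- function(fit, method = c("dahl", "mode")) {
  method <- match.arg(method)
  sol <- if (method == "dahl") dahl_select(fit$draws$z)
         else mode_assignment(fit$draws$z)
  out <- tibble(area_id = fit$area_ids, cluster = sol$labels, method = method)
  attr(out, "solution") <- sol
  out
}

#' Per-cluster coefficient summary table
#'
#' Posterior means and 95% HPD intervals of the cluster-level regression
#' coefficients, conditional on a point cluster configuration. Every
#' retained draw is first aligned to the solution labels (greedy
#' confusion-matrix matching, as in the posterior-mode method); the
#' coefficient draw attributed to cluster `g` is then the atom whose
#' members best overlap `g` in that draw. This is invariant to label
#' switching across draws; draws in which a cluster has no overlapping
#' atom are skipped for that cluster.
#'
#' @param fit An [sdp_gwr()] fit.
#' @param labels Optional label vector or tibble from [cluster_labels()];
#'   defaults to the Dahl configuration.
#' @param level HPD coverage level.
#' @return A tibble with one row per cluster and covariate: `cluster`,
#'   `size`, `term`, `estimate`, `hpd_lower`, `hpd_upper`, `n_draws` (the
#'   draws contributing). Clusters never matched in any draw are flagged
#'   with `NA` summaries rather than dropped.
#' @export
cluster_table <- function(fit, labels = NULL, level = 0.95) {
  if (is.null(labels)) labels <- cluster_labels(fit, "dahl")
  lab <- if (is.data.frame(labels)) labels$cluster else as.integer(labels)
  if (length(lab) != fit$n) abort("labels length does not match the fit")
  M <- nrow(fit$draws$z)
  K <- fit$K
  groups <- sort(unique(lab))
  draws_g <- array(NA_real_, c(M, length(groups), fit$p))
  for (m in seq_len(M)) {
    map <- .align_map(fit$draws$z[m, ], lab, K)
    Bm <- fit$draws$beta[m, , , drop = TRUE]
    if (is.null(dim(Bm))) Bm <- matrix(Bm, nrow = K)
    for (gi in seq_along(groups)) {
      k <- which(map == groups[gi])
      if (length(k)) draws_g[m, gi, ] <- Bm[k[1], ]
    }
  }
  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (j in seq_len(fit$p)) {
      dr <- draws_g[, gi, j]
      dr <- dr[!is.na(dr)]
      h <- if (length(dr) >= 2) hpd_interval(dr, level) else c(lower = NA_real_, upper = NA_real_)
      rows[[length(rows) + 1L]] <- tibble(
        cluster = g, size = sum(lab == g), term = fit$covariates[j],
        estimate = if (length(dr)) mean(dr) else NA_real_,
        hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
        n_draws = length(dr))
    }
  }
  bind_rows(rows)
}

#' @describeIn cluster_table Broom-style accessor: `tidy()` on a fit
#'   returns the Dahl-configuration cluster table.
#' @param x An `sdp_gwr_fit`.
#' @param ... Passed to `cluster_table()`.
#' @export
tidy.sdp_gwr_fit <- function(x, ...) cluster_table(x, ...)

#' One-row model summary
#'
#' WAIC (with its effective-parameter penalty), the number of occupied
#' clusters in the Dahl configuration, and sampler diagnostics.
#'
#' @param x An `sdp_gwr_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.sdp_gwr_fit <- function(x, ...) {
  w <- waic(x$pointwise_loglik)
  lab <- cluster_labels(x, "dahl")
  tibble(n = x$n, p = x$p, draws = nrow(x$draws$z),
         n_clusters = length(unique(lab$cluster)),
         waic = w$waic, lppd = w$lppd, p_waic = w$p_waic,
         accept_V = unname(x$acceptance["V"]),
         accept_b = unname(x$acceptance["b"]),
         runtime = x$runtime)
}

#' Per-area posterior coefficient estimates
#'
#' Posterior mean of the coefficient vector in effect at each area,
#' averaging `beta_{z_i}` over the retained draws. These are the
#' location-level estimates evaluated in replicate studies.
#'
#' @param fit An [sdp_gwr()] fit.
#' @return A tibble with `area_id` and one column per covariate.
#' @export
area_coefficients <- function(fit) {
  M <- nrow(fit$draws$z)
  acc <- matrix(0, fit$n, fit$p)
  for (m in seq_len(M)) {
    Bm <- fit$draws$beta[m, , , drop = TRUE]
    acc <- acc + Bm[fit$draws$z[m, ], , drop = FALSE]
  }
  out <- as_tibble(as.data.frame(acc / M))
  names(out) <- fit$covariates
  dplyr::bind_cols(tibble(area_id = fit$area_ids), out)
}
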