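#' Rand index between two partitions
#'
#' Fraction of unordered pairs of units on which the two labelings agree:
#' pairs placed together in both, plus pairs separated in both, over all
#' pairs. Invariant to relabelling of either argument; 1 means identical
#' partitions.
#'
#' @param a,b Label vectors of equal length (at least 2).
#' @return A scalar in `[0, 1]`.
#' @examples
#' rand_index(c(1, 1, 2), c(1, 2, 2))  # 1/3
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors differ in length")
  if (length(a) < 2) abort("need at least two units")
  ut <- upper.tri(matrix(0, length(a), length(a)))
  sa <- outer(a, a, `==`)[ut]
  sb <- outer(b, b, `==`)[ut]
  mean(sa == sb)
}

#' Replicate-study accuracy of coefficient estimates
#'
#' Per-covariate mean absolute bias (MAB), mean replicate standard
#' deviation (MSD) and mean of mean squared errors (MMSE) of per-area
#' coefficient estimates against the generating truth:
#' \deqn{MAB_k = \frac1n \sum_s \frac1R \sum_r |\hat\beta_{s,k,r} - \beta_{s,k}|}
#' \deqn{MSD_k = \frac1n \sum_s \sqrt{\frac1{R-1} \sum_r (\hat\beta_{s,k,r} -
#'   \bar{\hat\beta}_{s,k})^2}}
#' \deqn{MMSE_k = \frac1n \sum_s \frac1R \sum_r (\hat\beta_{s,k,r} - \beta_{s,k})^2}
#'
#' @param estimates A 3-d array of posterior estimates indexed
#'   (replicate, area, covariate).
#' @param truth A matrix of true coefficients indexed (area, covariate).
#' @return A tibble with one row per covariate: `term`, `mab`, `msd`,
#'   `mmse`. With a single replicate `msd` is `NA`.
#' @export
replicate_metrics <- function(estimates, truth) {
  dm <- dim(estimates)
  if (length(dm) != 3) abort("`estimates` must be (replicate, area, covariate)")
  if (!all(dm[2:3] == dim(truth))) abort("`truth` shape does not match")
  R <- dm[1]
  terms <- dimnames(estimates)[[3]] %||% paste0("x", seq_len(dm[3]))
  purrr::map_dfr(seq_len(dm[3]), function(k) {
    E <- estimates[, , k, drop = TRUE]
    if (R == 1) E <- matrix(E, nrow = 1)
    err <- sweep(E, 2, truth[, k])
    tibble(term = terms[k],
           mab = mean(colMeans(abs(err))),
           msd = if (R >= 2) mean(apply(E, 2, sd)) else NA_real_,
           mmse = mean(colMeans(err^2)))
  })
}

#' Widely applicable information criterion
#'
#' Computed from a draws-by-observations matrix of pointwise log
#' likelihoods, in log space: `lppd = sum_i log mean_d exp(ll[d, i])`,
#' `p_waic = sum_i var_d ll[d, i]`, `WAIC = -2 (lppd - p_waic)`.
#'
#' @param pointwise_loglik Matrix of pointwise log likelihoods (at least 2
#'   draws), e.g. `fit$pointwise_loglik`.
#' @return A list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(pointwise_loglik) {
  ll <- rbind(pointwise_loglik)
  if (nrow(ll) < 2) abort("need at least two draws for WAIC")
  lppd <- sum(apply(ll, 2, .log_mean_exp))
  p_waic <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

.log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}
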