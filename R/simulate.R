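#' Default generating cluster coefficients
#'
#' The three cluster-constant coefficient vectors (6 covariates each) used
#' by the default synthetic generator. They correspond to three regions
#' with well separated regression surfaces; the first covariate in
#' particular takes values -1.0, 0.62 and 2.31 across the regions.
#'
#' @return A 3 x 6 matrix (clusters by covariates).
#' @export
default_cluster_coefficients <- function() {
  rbind(c(-1.00, -0.04, -0.46, 1.29, 2.46, -1.05),
        c( 0.62, -0.29, -1.06, -0.06, 3.71, -0.51),
        c( 2.31,  0.29, -1.14, 0.53, 2.19, 0.37))
}

#' Lattice layout of areas with a fixed three-region partition
#'
#' A deterministic surrogate for a map of 159 contiguous areas: a jittered
#' rectangular lattice with rook contiguity, rescaled so the largest
#' centroid distance is 10, and split by coordinate thresholds into three
#' compact blocks of the requested sizes: the third region is the top slab
#' of the lattice and the first two split the remainder left/right. The
#' default gives 159 areas in regions of sizes 51, 49 and 59.
#'
#' @param n Number of areas.
#' @param partition Integer region sizes summing to `n`.
#' @param seed Seed for the centroid jitter (the lattice and partition are
#'   deterministic given `n` and `partition`).
#' @return A list with `graph` (an [area_graph()]) and `truth` (tibble of
#'   `area_id`, `cluster`).
#' @export
simulate_area_layout <- function(n = 159, partition = c(51, 49, 59),
                                 seed = NULL) {
  partition <- as.integer(partition)
  if (any(partition <= 0) || sum(partition) != n) {
    abort("`partition` must be positive sizes summing to n")
  }
  if (!is.null(seed)) set.seed(seed)
  nx <- ceiling(sqrt(n))
  col <- rep(seq_len(nx), each = nx)[seq_len(n)]
  row <- rep(seq_len(nx), times = nx)[seq_len(n)]
  ids <- sprintf("A%03d", seq_len(n))
  # rook contiguity on the lattice
  ef <- character(0); et <- character(0)
  for (i in seq_len(n)) {
    right <- which(col == col[i] + 1L & row == row[i])
    up <- which(col == col[i] & row == row[i] + 1L)
    for (j in c(right, up)) { ef <- c(ef, ids[i]); et <- c(et, ids[j]) }
  }
  jx <- runif(n, -0.15, 0.15); jy <- runif(n, -0.15, 0.15)
  cx <- col + jx; cy <- row + jy
  scale <- 10 / max(dist(cbind(cx, cy)))
  areas <- tibble(area_id = ids, lon = cx * scale, lat = cy * scale)
  g <- area_graph(areas, tibble(from = ef, to = et))
  cl <- integer(n)
  if (length(partition) == 3L) {
    # three compact block regions set by coordinate thresholds on the
    # (pre-jitter) lattice: the third region is the top slab, the first two
    # split the remainder left/right; thresholds are set by rank so the
    # sizes come out exactly as requested
    top <- order(row, col, decreasing = TRUE)[seq_len(partition[3])]
    cl[top] <- 3L
    rest <- setdiff(seq_len(n), top)
    lft <- rest[order(col[rest], row[rest])][seq_len(partition[1])]
    cl[lft] <- 1L
    cl[setdiff(rest, lft)] <- 2L
  } else {
    ord <- order(col, row)
    cl[ord] <- rep.int(seq_along(partition), partition)
  }
  list(graph = g, truth = tibble(area_id = ids, cluster = cl))
}

#' Spatially correlated covariates on a layout
#'
#' Draws `p` independent zero-mean Gaussian-process columns over the area
#' centroids with exponential covariance
#' `cov(x(s_i), x(s_j)) = exp(-||s_i - s_j|| / phi)` (unit variance on the
#' diagonal).
#'
#' @param graph An [area_graph()] supplying the centroids.
#' @param phi Positive range parameter of the exponential covariance.
#' @param p Number of covariate columns.
#' @param seed Optional seed.
#' @return An `n x p` matrix with columns named `x1, ..., xp`.
#' @export
simulate_covariates <- function(graph, phi = 0.9, p = 6, seed = NULL) {
  if (phi <= 0) abort("`phi` must be positive")
  if (!is.null(seed)) set.seed(seed)
  areas <- graph$areas
  D <- as.matrix(dist(cbind(areas$lon, areas$lat)))
  C <- exp(-D / phi)
  ch <- try(chol(C + diag(1e-10, nrow(C))), silent = TRUE)
  if (inherits(ch, "try-error")) {
    abort("covariance not positive definite even after jitter")
  }
  X <- crossprod(ch, matrix(rnorm(nrow(C) * p), nrow(C), p))
  dimnames(X) <- list(NULL, paste0("x", seq_len(p)))
  X
}

#' Simulate a clustered areal regression dataset
#'
#' Generates the synthetic study conditions: a lattice of `n` areas in
#' three fixed regions, `p` spatially correlated Gaussian-process
#' covariates (exponential covariance, range `phi`), cluster-constant true
#' coefficients per region, and independent Gaussian noise. With the
#' defaults this yields 159 areas with regions of sizes 51/49/59, 6
#' covariates with `phi = 0.9`, and noise standard deviation 0.5 (the
#' level implied by the width of the reference posterior intervals the
#' study conditions reproduce; see the methods vignette).
#'
#' @param n Number of areas.
#' @param p Number of covariates (must match `ncol(coefficients)`).
#' @param phi Gaussian-process range of the covariates.
#' @param partition Region sizes (length = number of clusters).
#' @param coefficients Cluster-by-covariate matrix of true coefficients.
#' @param noise_sd Standard deviation of the additive Gaussian errors.
#' @param seed Optional seed controlling layout jitter, covariates and
#'   noise.
#' @return A list of class `sdp_sim`: `data` (tibble `area_id`, `y`,
#'   `x1..xp`, `lon`, `lat`), `graph`, `truth` (tibble `area_id`,
#'   `cluster`), `coefficients`, and the generating settings.
#' @export
simulate_dataset <- function(n = 159, p = 6, phi = 0.9,
                             partition = c(51, 49, 59),
                             coefficients = default_cluster_coefficients(),
                             noise_sd = 0.5, seed = NULL) {
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != length(partition)) {
    abort("one coefficient row per region is required")
  }
  if (ncol(coefficients) != p) abort("`p` must match ncol(coefficients)")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  lay <- simulate_area_layout(n, partition)
  X <- simulate_covariates(lay$graph, phi, p)
  B <- coefficients[lay$truth$cluster, , drop = FALSE]
  y <- rowSums(X * B) + rnorm(n, 0, noise_sd)
  data <- dplyr::bind_cols(
    tibble(area_id = lay$graph$areas$area_id, y = y),
    as_tibble(as.data.frame(X)),
    lay$graph$areas[c("lon", "lat")])
  structure(list(data = data, graph = lay$graph, truth = lay$truth,
                 coefficients = coefficients,
                 settings = list(n = n, p = p, phi = phi,
                                 partition = partition, noise_sd = noise_sd,
                                 seed = seed)),
            class = "sdp_sim")
}

#' @export
print.sdp_sim <- function(x, ...) {
  cat(sprintf("<sdp_sim> %d areas, %d covariates, %d regions (%s), noise sd %.3g\n",
              x$settings$n, x$settings$p, length(x$settings$partition),
              paste(x$settings$partition, collapse = "/"), x$settings$noise_sd))
  invisible(x)
}
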