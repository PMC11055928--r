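#' Read and write area tables and edge lists
#'
#' The on-disk interchange formats are plain delimited text: an area table
#' with columns `area_id`, `y`, `x1..xp`, `lon`, `lat` (header required)
#' and a two-column edge list of area-id pairs.
#'
#' @param path File path.
#' @param data A data frame to write.
#' @param log_transform Apply `log()` elementwise to the response and
#'   covariates on read (for positive-valued data analysed on the log
#'   scale).
#' @return `read_area_data()` returns a tibble; writers return `path`
#'   invisibly.
#' @name area_io
NULL

#' @rdname area_io
#' @export
read_area_data <- function(path, log_transform = FALSE) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("area_id", "y", "lon", "lat") %in% names(d))) {
    abort("area table must have columns area_id, y, lon, lat")
  }
  d$area_id <- as.character(d$area_id)
  if (log_transform) {
    cols <- c("y", .default_covariates(d))
    for (cl in cols) {
      if (any(d[[cl]] <= 0)) abort(sprintf("log transform: column %s not positive", cl))
      d[[cl]] <- log(d[[cl]])
    }
  }
  d
}

#' @rdname area_io
#' @export
write_area_data <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname area_io
#' @export
read_edge_list <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(d) < 2) abort("edge list must have two columns")
  tibble(from = as.character(d[[1]]), to = as.character(d[[2]]))
}

#' @rdname area_io
#' @export
write_edge_list <- function(edges, path) {
  readr::write_csv(edges, path)
  invisible(path)
}

#' @rdname area_io
#' @param edges An edge tibble.
NULL

#' Write a draw archive
#'
#' Persists the retained draws of a fit as a directory of columnar text
#' tables (one file per parameter block) plus a JSON run manifest holding
#' the seed, configuration, acceptance rates and input digests, so a run
#' can be summarized later or reproduced.
#'
#' @param fit An [sdp_gwr()] fit.
#' @param dir Output directory (created if missing).
#' @param inputs Optional named character vector of input file paths whose
#'   MD5 digests are recorded in the manifest.
#' @return The directory path, invisibly.
#' @export
write_draw_archive <- function(fit, dir, inputs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) {
    readr::write_csv(as.data.frame(m), file.path(dir, f), col_names = TRUE)
  }
  wr(fit$draws$z, "z.csv")
  wr(fit$draws$sigma2, "sigma2.csv")
  wr(fit$draws$V, "V.csv")
  wr(data.frame(b = fit$draws$b), "b.csv")
  wr(fit$pointwise_loglik, "pointwise_loglik.csv")
  M <- dim(fit$draws$beta)[1]
  beta_flat <- matrix(fit$draws$beta, nrow = M)
  colnames(beta_flat) <- as.vector(outer(seq_len(fit$K), fit$covariates,
                                         function(k, v) paste0("k", k, ".", v)))
  wr(beta_flat, "beta.csv")
  manifest <- list(
    package = "sdpgwr",
    version = as.character(utils::packageVersion("sdpgwr")),
    created = format(Sys.time(), tz = "UTC"),
    seed = fit$chain$seed,
    n = fit$n, p = fit$p, K = fit$K,
    covariates = fit$covariates,
    area_ids = fit$area_ids,
    likelihood_mode = fit$config$likelihood_mode,
    distance = fit$config$distance,
    kernel = fit$config$stick$kernel,
    bandwidth_prior = fit$config$stick$bandwidth_prior,
    knots = fit$config$stick$knots,
    chain = unclass(fit$chain),
    acceptance = as.list(fit$acceptance),
    runtime = fit$runtime,
    input_digests = if (!is.null(inputs)) as.list(tools::md5sum(inputs)) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a draw archive
#'
#' @param dir Directory written by [write_draw_archive()].
#' @return A list with `draws` (`z`, `beta`, `sigma2`, `V`, `b`),
#'   `pointwise_loglik` and `manifest`; the shape mirrors an
#'   [sdp_gwr()] fit closely enough for [dahl_select()], [waic()] and
#'   [cluster_table()]-style summaries.
#' @export
read_draw_archive <- function(dir) {
  need <- c("z.csv", "beta.csv", "sigma2.csv", "V.csv", "b.csv",
            "pointwise_loglik.csv", "manifest.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    abort(paste0("corrupt archive, missing: ", paste(missing, collapse = ", ")))
  }
  rd <- function(f) as.matrix(readr::read_csv(file.path(dir, f),
                                              show_col_types = FALSE))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  z <- rd("z.csv"); storage.mode(z) <- "integer"
  beta_flat <- rd("beta.csv")
  M <- nrow(z)
  beta <- array(beta_flat, c(M, man$K, man$p),
                dimnames = list(NULL, NULL, man$covariates))
  structure(list(
    draws = list(z = z, beta = beta, sigma2 = rd("sigma2.csv"),
                 V = rd("V.csv"), b = drop(rd("b.csv"))),
    pointwise_loglik = rd("pointwise_loglik.csv"),
    manifest = man,
    area_ids = man$area_ids, covariates = man$covariates,
    n = man$n, p = man$p, K = man$K
  ), class = c("sdp_draw_archive"))
}
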