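#' Build an areal adjacency graph
#'
#' Areal (lattice) data live on a graph whose nodes are the areas and whose
#' edges join contiguous areas. The graph carries the area centroids, from
#' which graph-step and great-circle distance matrices are derived for the
#' geographically weighted likelihood.
#'
#' @param areas A data frame with one row per area. Must contain a unique
#'   `area_id` column and centroid coordinate columns `lon` and `lat`
#'   (planar `x`/`y` coordinates may be supplied under the same names).
#' @param edges A data frame (or two-column matrix) of contiguity edges; the
#'   first two columns are area-id pairs. Self-edges are dropped with a
#'   warning and duplicate edges (in either orientation) are collapsed.
#'
#' @return An object of class `area_graph`: a list with `areas` (tibble),
#'   `edges` (tibble of normalized `from`/`to` pairs) and `graph` (an
#'   [igraph::graph] used for shortest paths).
#'
#' @examples
#' areas <- tibble::tibble(area_id = c("a", "b", "c"),
#'                         lon = c(0, 1, 2), lat = c(0, 0, 0))
#' g <- area_graph(areas, data.frame(from = c("a", "b"), to = c("b", "c")))
#' graph_distances(g)["a", "c"]   # two steps along the chain
#' @export
area_graph <- function(areas, edges) {
  areas <- as_tibble(areas)
  if (!all(c("area_id", "lon", "lat") %in% names(areas))) {
    abort("`areas` must have columns area_id, lon and lat")
  }
  areas$area_id <- as.character(areas$area_id)
  if (anyDuplicated(areas$area_id)) {
    abort(paste0("duplicate area id: ",
                 paste(unique(areas$area_id[duplicated(areas$area_id)]), collapse = ", ")))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) abort("`edges` must have two columns of area-id pairs")
  ed <- tibble(from = as.character(edges[[1]]), to = as.character(edges[[2]]))
  unknown <- setdiff(c(ed$from, ed$to), areas$area_id)
  if (length(unknown)) {
    abort(paste0("edge list refers to unknown area id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  self <- ed$from == ed$to
  if (any(self)) {
    warn(sprintf("dropped %d self-edge(s)", sum(self)))
    ed <- ed[!self, , drop = FALSE]
  }
  # collapse duplicates irrespective of orientation
  key <- ifelse(ed$from < ed$to, paste(ed$from, ed$to), paste(ed$to, ed$from))
  ed <- ed[!duplicated(key), , drop = FALSE]
  swap <- ed$from > ed$to
  tmp <- ed$from[swap]; ed$from[swap] <- ed$to[swap]; ed$to[swap] <- tmp
  ed <- dplyr::arrange(ed, .data$from, .data$to)
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = areas$area_id, stringsAsFactors = FALSE))
  structure(list(areas = areas, edges = ed, graph = g), class = "area_graph")
}

#' @export
print.area_graph <- function(x, ...) {
  cat(sprintf("<area_graph> %d areas, %d contiguity edges, %d connected component(s)\n",
              nrow(x$areas), nrow(x$edges),
              igraph::count_components(x$graph)))
  invisible(x)
}

#' Number of areas in an area graph
#' @param graph An [area_graph()].
#' @return Integer number of areas.
#' @export
n_areas <- function(graph) nrow(graph$areas)

#' Graph-step distance matrix
#'
#' Shortest-path distance between every pair of areas, counted in edges.
#' Pairs in different connected components are unreachable and receive the
#' sentinel `Inf`; the weight kernel maps that sentinel to weight zero.
#'
#' @param graph An [area_graph()].
#' @return An `n x n` symmetric matrix with zero diagonal, dimnames set to
#'   the area ids, and `Inf` marking unreachable pairs.
#' @export
graph_distances <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  d <- igraph::distances(graph$graph)
  d <- d[graph$areas$area_id, graph$areas$area_id]
  d
}

#' Great-circle distance matrix
#'
#' Haversine distances between area centroids interpreted as (lon, lat) in
#' decimal degrees, on a sphere of the given radius.
#'
#' @param graph An [area_graph()], or a data frame with `lon`/`lat` columns.
#' @param radius Sphere radius; the distances are in the same unit.
#'   Defaults to the Earth's mean radius in kilometres.
#' @return An `n x n` symmetric nonnegative matrix with zero diagonal.
#' @export
great_circle_distances <- function(graph, radius = 6371) {
  areas <- if (inherits(graph, "area_graph")) graph$areas else as_tibble(graph)
  if (any(areas$lat < -90 | areas$lat > 90)) {
    abort("latitude out of range [-90, 90]")
  }
  m <- cbind(areas$lon, areas$lat)
  d <- geosphere::distm(m, fun = geosphere::distHaversine)
  # distHaversine works on its default Earth radius; rescale linearly
  d <- d * (radius / 6378137)
  dimnames(d) <- list(areas$area_id, areas$area_id)
  d
}

#' Geographically weighted regression weights
#'
#' Distance-decay observation weights for the local likelihood at each
#' location. An observation at distance `d` from the focal location gets
#' weight 1 when `d <= threshold` and `exp(-d / bandwidth)` otherwise;
#' unreachable pairs (distance `Inf`) get weight 0.
#'
#' With graph-step distances the default `threshold = 1` gives the focal
#' area and its direct neighbours full weight. For continuous metrics such
#' as great-circle distances, `threshold = 0` restricts full weight to the
#' focal area itself.
#'
#' @param distances A distance matrix, e.g. from [graph_distances()].
#' @param bandwidth Positive decay bandwidth `b`.
#' @param threshold Distance at or below which the weight is exactly 1.
#' @return A matrix of the same shape with entries in `[0, 1]`; row `i`
#'   holds the diagonal of the weight matrix `W(s_i)`.
#' @examples
#' gwr_weight_kernel(10, bandwidth = 100)   # exp(-10/100) = 0.904
#' @export
gwr_weights <- function(distances, bandwidth, threshold = 1) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0) {
    abort("`bandwidth` must be a positive scalar")
  }
  w <- exp(-distances / bandwidth)
  w[distances <= threshold] <- 1
  w[is.infinite(distances)] <- 0
  attr(w, "bandwidth") <- bandwidth
  attr(w, "threshold") <- threshold
  w
}

#' @rdname gwr_weights
#' @param d Distance (scalar or vector) at which to evaluate the kernel.
#' @export
gwr_weight_kernel <- function(d, bandwidth, threshold = 1) {
  as.vector(gwr_weights(rbind(d), bandwidth, threshold))
}

#' Read an areal graph from a GeoJSON polygon file
#'
#' A lightweight reader for GeoJSON `FeatureCollection`s of polygons:
#' centroids are computed by the shoelace formula on each feature's outer
#' ring and queen contiguity (any shared vertex, coordinates rounded to
#' `digits`) defines the edges. Intended for modest files; no geometry
#' library is required.
#'
#' @param path Path to a GeoJSON file of Polygon/MultiPolygon features with
#'   an id property (`id_property`, default "area_id").
#' @param id_property Name of the feature property holding the area id.
#' @param digits Vertices are rounded to this many digits before testing
#'   for shared points.
#' @return An [area_graph()].
#' @export
area_graph_from_geojson <- function(path, id_property = "area_id", digits = 6) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) abort("not a GeoJSON FeatureCollection")
  rings <- list(); ids <- character(length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties[[id_property]] %||% f$id
    if (is.null(id)) abort(sprintf("feature %d has no '%s' property", i, id_property))
    ids[i] <- as.character(id)
    geom <- f$geometry
    coords <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      abort(sprintf("unsupported geometry type '%s'", geom$type)))
    rings[[i]] <- lapply(coords, function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    })
  }
  cent <- t(vapply(rings, .rings_centroid, numeric(2)))
  areas <- tibble(area_id = ids, lon = cent[, 1], lat = cent[, 2])
  vert <- lapply(rings, function(rs) {
    unique(do.call(rbind, lapply(rs, function(r) round(r, digits))))
  })
  ef <- character(); et <- character()
  for (i in seq_along(vert)) {
    for (j in seq_len(i - 1L)) {
      a <- vert[[i]]; b <- vert[[j]]
      shared <- any(paste(a[, 1], a[, 2]) %in% paste(b[, 1], b[, 2]))
      if (shared) { ef <- c(ef, ids[j]); et <- c(et, ids[i]) }
    }
  }
  area_graph(areas, tibble(from = ef, to = et))
}

# area-weighted centroid of one or more shoelace rings
.rings_centroid <- function(rs) {
  acc <- c(0, 0); atot <- 0
  for (r in rs) {
    x <- r[, 1]; y <- r[, 2]
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    cr <- x * y2 - x2 * y
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) { c0 <- c(mean(x), mean(y)); a <- 1e-12 }
    else c0 <- c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
    acc <- acc + abs(a) * c0; atot <- atot + abs(a)
  }
  acc / atot
}
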