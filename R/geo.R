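# Municipality geometry: centroid distances (great-circle or planar) and
# spatial neighborhood structures (queen contiguity, k-nearest neighbors).

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between coordinate pairs
#'
#' Haversine formula on a sphere of radius 6371.0 km. All arguments are
#' recycled to a common length.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distances in kilometers.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

geo_metric <- function(geos, metric = NULL) {
  if (!is.null(metric)) return(match.arg(metric, c("planar", "haversine")))
  if (all(c("x", "y") %in% names(geos))) "planar" else "haversine"
}

#' Pairwise distance matrix between municipality centroids
#'
#' Uses planar Euclidean distance when the geometry table has `x`/`y`
#' columns (kilometers, as produced by the synthetic generator), or the
#' haversine great-circle distance for `lat`/`lon` columns. The metric can be
#' forced with `metric`.
#'
#' @param geos `data.frame` with `municipality_id` and either `x`,`y` (km) or
#'   `lat`,`lon` (degrees).
#' @param metric `NULL` (auto), `"planar"` or `"haversine"`.
#' @return Symmetric matrix of kilometers with ids as dimnames.
#' @export
distance_matrix <- function(geos, metric = NULL) {
  metric <- geo_metric(geos, metric)
  ids <- as.character(geos$municipality_id)
  if (anyDuplicated(ids)) stop("municipality ids must be unique")
  if (metric == "planar") {
    D <- as.matrix(stats::dist(cbind(geos$x, geos$y)))
  } else {
    n <- nrow(geos)
    D <- outer(seq_len(n), seq_len(n), function(i, j) {
      haversine_km(geos$lat[i], geos$lon[i], geos$lat[j], geos$lon[j])
    })
  }
  dimnames(D) <- list(ids, ids)
  D
}

new_adjacency <- function(neighbors, kind) {
  structure(list(neighbors = neighbors, kind = kind), class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("adjacency (%s): %d units, mean degree %.2f, %d isolated\n",
              x$kind, length(deg), mean(deg), sum(deg == 0)))
  invisible(x)
}

#' k-nearest-neighbor adjacency
#'
#' Each municipality is linked to its `k` nearest neighbors by centroid
#' distance; the relation is then symmetrized by union so that
#' `i in N(j) <=> j in N(i)`. Distance ties are broken by ascending
#' municipality id, making the result deterministic.
#'
#' @param geos Geometry table (see [distance_matrix()]).
#' @param k Number of nearest neighbors, default 8.
#' @param metric Distance metric override.
#' @return An `adjacency` object: named list of neighbor id vectors.
#' @export
knn_adjacency <- function(geos, k = 8, metric = NULL) {
  n <- nrow(geos)
  if (k <= 0 || k >= n) stop("k must be in 1..(number of units - 1)")
  D <- distance_matrix(geos, metric)
  ids <- rownames(D)
  nb <- vector("list", n)
  names(nb) <- ids
  for (i in seq_len(n)) {
    ord <- order(D[i, ], ids)        # ties broken by ascending id
    ord <- ord[ord != i]
    nb[[i]] <- ids[ord[seq_len(k)]]
  }
  # union symmetrization
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!(ids[i] %in% nb[[j]])) nb[[j]] <- c(nb[[j]], ids[i])
    }
  }
  nb <- lapply(nb, function(v) sort(v))
  new_adjacency(nb, "knn")
}

polygon_vertex_keys <- function(poly, digits = 6) {
  m <- round(poly, digits)
  unique(paste(m[, 1], m[, 2], sep = "_"))
}

#' Queen-contiguity adjacency from polygons
#'
#' Two municipalities are neighbors when their boundaries share at least one
#' point (a common edge or a single corner). Sharing is detected by matching
#' boundary vertices after rounding coordinates to `digits` decimals, which
#' is exact for lattice tessellations and for administrative boundary files
#' whose shared borders carry identical vertex chains. A shared edge whose
#' endpoints are not common vertices of both rings is not detected.
#'
#' Municipalities with no neighbor (islands) are allowed and produce a
#' warning listing their ids.
#'
#' @param polygons Named list (ids as names) of two-column coordinate
#'   matrices, one ring per municipality (closed or open rings both accepted),
#'   or a list of such matrices per id (multi-part geometries).
#' @param digits Coordinate rounding used for vertex matching.
#' @return An `adjacency` object.
#' @export
queen_adjacency <- function(polygons, digits = 6) {
  ids <- names(polygons)
  if (is.null(ids) || any(ids == "")) stop("polygons must be a named list")
  missing_poly <- ids[!vapply(polygons, function(p) {
    is.matrix(p) || (is.list(p) && length(p) > 0)
  }, logical(1))]
  if (length(missing_poly)) {
    stop("missing polygon for: ", paste(missing_poly, collapse = ", "))
  }
  keys <- lapply(polygons, function(p) {
    if (is.matrix(p)) polygon_vertex_keys(p, digits)
    else unique(unlist(lapply(p, polygon_vertex_keys, digits = digits)))
  })
  # invert: vertex key -> polygons touching it
  flat <- data.frame(key = unlist(keys, use.names = FALSE),
                     id = rep(ids, lengths(keys)),
                     stringsAsFactors = FALSE)
  by_key <- split(flat$id, flat$key)
  nb <- stats::setNames(vector("list", length(ids)), ids)
  for (grp in by_key) {
    if (length(grp) < 2) next
    for (id in grp) nb[[id]] <- c(nb[[id]], setdiff(grp, id))
  }
  nb <- lapply(nb, function(v) if (is.null(v)) character(0) else sort(unique(v)))
  isolated <- ids[lengths(nb) == 0]
  if (length(isolated)) {
    warning("isolated units (no queen neighbor): ",
            paste(isolated, collapse = ", "))
  }
  new_adjacency(nb, "queen")
}

#' Adjacency as an edge list
#'
#' @param adj An `adjacency` object.
#' @return `data.frame` with columns `id_a`, `id_b`, each undirected edge
#'   once with `id_a < id_b`.
#' @export
adjacency_edges <- function(adj) {
  a <- rep(names(adj$neighbors), lengths(adj$neighbors))
  b <- unlist(adj$neighbors, use.names = FALSE)
  keep <- a < b
  out <- data.frame(id_a = a[keep], id_b = b[keep], stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Read municipality centroids from CSV
#'
#' Accepts either `municipality_id,lat,lon` (degrees) or
#' `municipality_id,x,y` (planar km).
#'
#' @param path CSV path.
#' @return Geometry `data.frame`.
#' @export
read_centroids_csv <- function(path) {
  g <- utils::read.csv(path, colClasses = c(municipality_id = "character"))
  if (!("municipality_id" %in% names(g)) ||
      !(all(c("lat", "lon") %in% names(g)) || all(c("x", "y") %in% names(g)))) {
    stop("centroid CSV needs municipality_id plus lat/lon or x/y")
  }
  g
}

#' Read municipality polygons from a GeoJSON FeatureCollection
#'
#' Each feature must carry a `municipality_id` property and a Polygon or
#' MultiPolygon geometry. Centroids are computed as the mean of the outer
#' ring vertices (sufficient for neighbor construction and synthetic maps).
#'
#' @param path GeoJSON path.
#' @return List with `geos` (centroid `data.frame`; planar or lat/lon columns
#'   depending on `planar`) and `polygons` (named list of rings).
#' @param planar If `TRUE`, coordinates are interpreted as planar km
#'   (`x`/`y`); otherwise as lon/lat degrees.
#' @export
read_geojson_polygons <- function(path, planar = FALSE) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  polys <- list()
  cx <- cy <- numeric(0)
  for (f in gj$features) {
    id <- as.character(f$properties$municipality_id)
    ring_to_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    }
    g <- f$geometry
    if (g$type == "Polygon") {
      rings <- lapply(g$coordinates, ring_to_mat)
    } else if (g$type == "MultiPolygon") {
      rings <- unlist(lapply(g$coordinates,
                             function(pp) lapply(pp, ring_to_mat)),
                      recursive = FALSE)
    } else {
      stop("unsupported geometry type: ", g$type)
    }
    polys[[id]] <- rings
    outer_ring <- rings[[1]]
    # drop duplicated closing vertex before averaging
    if (nrow(outer_ring) > 1 &&
        all(outer_ring[1, ] == outer_ring[nrow(outer_ring), ])) {
      outer_ring <- outer_ring[-nrow(outer_ring), , drop = FALSE]
    }
    cx <- c(cx, mean(outer_ring[, 1]))
    cy <- c(cy, mean(outer_ring[, 2]))
  }
  geos <- if (planar) {
    data.frame(municipality_id = names(polys), x = cx, y = cy,
               stringsAsFactors = FALSE)
  } else {
    data.frame(municipality_id = names(polys), lat = cy, lon = cx,
               stringsAsFactors = FALSE)
  }
  list(geos = geos, polygons = polys)
}

#' Median nearest-neighbor distance
#'
#' Default kernel scale for Tango's clustering statistic.
#'
#' @param D Symmetric distance matrix.
#' @return Scalar kilometers.
#' @export
median_nn_distance <- function(D) {
  diag(D) <- Inf
  stats::median(apply(D, 1, min))
}
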