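#' Polygon features: construction, GeoJSON interchange, containment
#'
#' Polygon maps (potential-vegetation units, habitat masks, ecoregions,
#' intact-forest areas) travel as GeoJSON FeatureCollections. Inside R a
#' feature is a plain list: `type` (`"Polygon"` or `"Point"`), `rings` (for
#' polygons, a list of two-column lon/lat matrices, exterior ring first) or
#' `coords` (for points), and `properties` (named list). Containment uses
#' an even-odd ray cast with an explicit boundary rule: a point exactly on
#' an edge or vertex counts as inside, and when several features contain a
#' point the first in file order wins — deterministic by construction.
#'
#' @name geometry
NULL

#' Build a polygon feature
#'
#' @param rings list of two-column matrices (lon, lat); exterior ring first,
#'   further rings are holes. Rings need not repeat their first vertex.
#' @param properties named list of feature properties.
#' @return A feature list usable with [locate_points] and [write_geojson].
#' @export
polygon_feature <- function(rings, properties = list()) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2L, nrow(r) >= 3L)
    unname(r)
  })
  list(type = "Polygon", rings = rings, properties = properties)
}

#' Axis-aligned rectangle feature
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds in decimal degrees.
#' @inheritParams polygon_feature
#' @export
rect_feature <- function(xmin, xmax, ymin, ymax, properties = list()) {
  polygon_feature(cbind(c(xmin, xmax, xmax, xmin),
                        c(ymin, ymin, ymax, ymax)), properties)
}

# TRUE where (lon, lat) lies on the boundary of ring r (within tol degrees).
on_ring_edge <- function(lon, lat, r, tol = 1e-9) {
  out <- rep(FALSE, length(lon))
  nv <- nrow(r)
  for (e in seq_len(nv)) {
    x1 <- r[e, 1L]; y1 <- r[e, 2L]
    x2 <- r[if (e == nv) 1L else e + 1L, 1L]
    y2 <- r[if (e == nv) 1L else e + 1L, 2L]
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    seg <- abs(cross) <= tol * max(1, abs(x2 - x1) + abs(y2 - y1)) &
      lon >= pmin(x1, x2) - tol & lon <= pmax(x1, x2) + tol &
      lat >= pmin(y1, y2) - tol & lat <= pmax(y1, y2) + tol
    out <- out | seg
  }
  out
}

#' Point-in-polygon test
#'
#' Even-odd ray cast over all rings of a polygon feature (holes handled
#' automatically); boundary points count as inside.
#'
#' @param lon,lat numeric vectors of point coordinates.
#' @param feature a polygon feature.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, feature) {
  stopifnot(feature$type == "Polygon")
  inside <- rep(FALSE, length(lon))
  boundary <- rep(FALSE, length(lon))
  for (r in feature$rings) {
    boundary <- boundary | on_ring_edge(lon, lat, r)
    nv <- nrow(r)
    for (e in seq_len(nv)) {
      x1 <- r[e, 1L]; y1 <- r[e, 2L]
      x2 <- r[if (e == nv) 1L else e + 1L, 1L]
      y2 <- r[if (e == nv) 1L else e + 1L, 2L]
      if (y1 == y2) next
      crosses <- ((y1 > lat) != (y2 > lat)) &
        (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
  }
  inside | boundary
}

#' Assign points to the first containing feature
#'
#' @param lon,lat numeric vectors of point coordinates.
#' @param features list of polygon features (file order).
#' @return Integer vector: index of the first feature containing each point,
#'   `NA` for points outside all features.
#' @export
locate_points <- function(lon, lat, features) {
  idx <- rep(NA_integer_, length(lon))
  for (f in seq_along(features)) {
    open <- is.na(idx)
    if (!any(open)) break
    hit <- point_in_polygon(lon[open], lat[open], features[[f]])
    idx[open][hit] <- f
  }
  idx
}

#' Read / write GeoJSON FeatureCollections
#'
#' `read_geojson` parses a GeoJSON FeatureCollection of Polygon,
#' MultiPolygon or Point features into the package's feature lists
#' (MultiPolygons are flattened to one polygon feature holding all rings).
#' `write_geojson` performs the inverse.
#'
#' @param path file path.
#' @param features list of feature lists.
#' @return `read_geojson`: list of features in file order.
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  lapply(g$features, function(f) {
    geom <- f$geometry
    props <- lapply(f$properties, function(p)
      if (is.list(p)) unlist(p, use.names = FALSE) else p)
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    if (geom$type == "Point") {
      list(type = "Point",
           coords = c(geom$coordinates[[1]], geom$coordinates[[2]]),
           properties = props)
    } else if (geom$type == "Polygon") {
      polygon_feature(lapply(geom$coordinates, ring_mat), props)
    } else if (geom$type == "MultiPolygon") {
      rings <- unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ring_mat)), recursive = FALSE)
      polygon_feature(rings, props)
    } else stop("unsupported geometry type: ", geom$type, call. = FALSE)
  })
}

#' @rdname read_geojson
#' @export
write_geojson <- function(features, path) {
  close_ring <- function(r) {
    if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
  }
  feats <- lapply(features, function(f) {
    geom <- if (f$type == "Point") {
      list(type = "Point", coordinates = c(f$coords[1L], f$coords[2L]))
    } else {
      list(type = "Polygon", coordinates = lapply(f$rings, close_ring))
    }
    list(type = "Feature", properties = f$properties, geometry = geom)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}
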