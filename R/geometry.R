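#' Great-circle (haversine) distance matrix
#'
#' Pairwise spherical distances between two point sets, on a sphere of radius
#' 6,371,000 m. One degree of latitude is then ~111,195 m, matching the usual
#' epidemiological convention for sub-kilometre catchments.
#'
#' @param a,b data frames with `lat` and `lon` columns (degrees).
#' @param radius_m sphere radius in metres.
#' @return numeric matrix of dimension `nrow(a)` x `nrow(b)`, in metres.
#' @examples
#' haversine_matrix(data.frame(lat = 0, lon = 0), data.frame(lat = 1, lon = 0))
#' @export
haversine_matrix <- function(a, b, radius_m = 6371000) {
  check_lonlat(a, "points_a")
  check_lonlat(b, "points_b")
  deg2rad <- pi / 180
  la <- a$lat * deg2rad
  lb <- b$lat * deg2rad
  oa <- a$lon * deg2rad
  ob <- b$lon * deg2rad
  # haversine: d = 2R asin( sqrt( sin^2(dphi/2) + cos(phi1)cos(phi2) sin^2(dlam/2) ) )
  sdlat <- sin(outer(lb, la, "-") / 2)
  sdlon <- sin(outer(ob, oa, "-") / 2)
  h <- t(sdlat^2 + outer(cos(lb), cos(la)) * sdlon^2)
  2 * radius_m * asin(pmin(sqrt(h), 1)) # pmin keeps h's dim attributes
}

# ---- point-in-polygon (even-odd ray casting) --------------------------------

#' Even-odd ray-casting containment test for one ring
#'
#' `ring` is a two-column matrix (lon, lat); the ring may be open or closed.
#' Points exactly on an edge are resolved by the half-open crossing rule
#' (deterministic, but callers should avoid boundary points where possible).
#' @noRd
point_in_ring <- function(lon, lat, ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- length(x)
  if (isTRUE(all.equal(c(x[1], y[1]), c(x[n], y[n])))) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > lat) != (y[j] > lat)) &
      (lon < (x[j] - x[i]) * (lat - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test points against a multipolygon (list of polygons, each a list of rings)
#'
#' A point is inside a polygon when the even-odd rule over its rings (outer
#' ring plus holes) says so, and inside the multipolygon when inside any of
#' its polygons.
#' @noRd
point_in_multipolygon <- function(lon, lat, multipolygon) {
  inside <- rep(FALSE, length(lon))
  for (poly in multipolygon) {
    in_poly <- rep(FALSE, length(lon))
    for (ring in poly) {
      in_poly <- xor(in_poly, point_in_ring(lon, lat, ring))
    }
    inside <- inside | in_poly
  }
  inside
}

# ---- GeoJSON ---------------------------------------------------------------

#' Read municipality polygons from a GeoJSON FeatureCollection
#'
#' Features must be Polygon or MultiPolygon geometries; a `municipality_id`
#' property is used when present (feature order otherwise). Any other
#' properties (e.g. `urban_rural`) are carried through.
#'
#' @param path path to a GeoJSON file.
#' @return a list with `municipalities` (tibble of properties) and `polygons`
#'   (list, one multipolygon per municipality; each polygon a list of rings,
#'   each ring a 2-column lon/lat matrix).
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  assert_that_(identical(gj$type, "FeatureCollection"),
               "expected a GeoJSON FeatureCollection")
  feats <- gj$features
  polys <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    geom <- f$geometry
    coords <- geom$coordinates
    mp <- switch(geom$type,
      Polygon = list(coords),
      MultiPolygon = coords,
      stop(sprintf("feature %d: unsupported geometry '%s'", k, geom$type),
           call. = FALSE)
    )
    polys[[k]] <- lapply(mp, function(poly) {
      lapply(poly, function(ring) {
        do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      })
    })
    p <- f$properties %||% list()
    p$municipality_id <- p$municipality_id %||% k
    props[[k]] <- p
  }
  municipalities <- dplyr::bind_rows(lapply(props, tibble::as_tibble))
  names(polys) <- as.character(municipalities$municipality_id)
  list(municipalities = municipalities, polygons = polys)
}

#' @noRd
ring_to_geojson <- function(ring) {
  ring <- as.matrix(ring)
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ]))) {
    ring <- rbind(ring, ring[1, ])
  }
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Write municipality multipolygons and properties as GeoJSON
#'
#' @param municipalities data frame of feature properties, one row per
#'   municipality (must contain `municipality_id`).
#' @param polygons list of multipolygons parallel to `municipalities`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(municipalities, polygons, path) {
  feats <- lapply(seq_len(nrow(municipalities)), function(k) {
    list(
      type = "Feature",
      properties = as.list(municipalities[k, , drop = FALSE]),
      geometry = list(
        type = "MultiPolygon",
        coordinates = lapply(polygons[[k]], function(poly) {
          lapply(poly, ring_to_geojson)
        })
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write grid cells as a GeoJSON FeatureCollection of square polygons
#'
#' Each cell becomes one Polygon feature whose properties are the remaining
#' columns of `cells` (access scores, predictions, ranks, ...).
#'
#' @param cells tibble from [build_grid()] (optionally with extra columns).
#' @param cell_size_deg cell edge length in degrees.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(cells, cell_size_deg, path) {
  half <- cell_size_deg / 2
  prop_cols <- setdiff(names(cells), c("centroid_lat", "centroid_lon"))
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    cx <- cells$centroid_lon[i]
    cy <- cells$centroid_lat[i]
    ring <- list(
      c(cx - half, cy - half), c(cx + half, cy - half),
      c(cx + half, cy + half), c(cx - half, cy + half),
      c(cx - half, cy - half)
    )
    list(
      type = "Feature",
      properties = as.list(cells[i, prop_cols, drop = FALSE]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
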