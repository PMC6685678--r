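# Small in-code fixtures shared across tests.

# A unit-degree grid anchored at (0, 0): r rows x c cols of `size`-degree cells.
toy_grid <- function(rows = 2, cols = 2, size = 0.01) {
  build_grid(c(lon_min = 0, lon_max = cols * size,
               lat_min = 0, lat_max = rows * size), size)
}

# A square Polygon ring (closed), lon/lat bounds.
square_ring <- function(lon0, lat0, lon1, lat1) {
  cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
        lat = c(lat0, lat0, lat1, lat1, lat0))
}

# region object with rectangular municipalities given as bounds rows
# (data.frame: municipality_id, lon0, lat0, lon1, lat1)
toy_region <- function(bounds) {
  polys <- lapply(seq_len(nrow(bounds)), function(k) {
    b <- bounds[k, ]
    list(list(square_ring(b$lon0, b$lat0, b$lon1, b$lat1)))
  })
  names(polys) <- as.character(bounds$municipality_id)
  list(municipalities = tibble::tibble(municipality_id = bounds$municipality_id),
       polygons = polys)
}

# random small coverage problems for solver cross-checks
random_coverage_problem <- function(n_ohca, n_sites, budget, density = 0.3) {
  a <- matrix(rbinom(n_ohca * n_sites, 1, density), n_ohca, n_sites)
  coverage_problem(a, budget)
}
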