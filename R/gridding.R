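#' Build a regular lon/lat grid over a bounding box
#'
#' Cells are squares of `cell_size_deg` degrees, anchored at the lower-left
#' corner of the bounding box and tiled row-major from the south-west. Cell
#' boundaries are half-open, `[x, x + size)` in both axes, so every point of
#' the bounded plane maps to exactly one cell.
#'
#' @param bbox named numeric vector with `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max` (degrees).
#' @param cell_size_deg cell edge length in degrees (default 0.01, roughly a
#'   1.1 km cell at mid latitudes).
#' @return tibble with columns `cell_id`, `row`, `col`, `centroid_lat`,
#'   `centroid_lon`; the grid geometry is also attached as the `grid_spec`
#'   attribute (origin, cell size, dimensions).
#' @examples
#' g <- build_grid(c(lon_min = 0, lon_max = 0.03, lat_min = 0, lat_max = 0.02))
#' nrow(g) # 6
#' @export
build_grid <- function(bbox, cell_size_deg = 0.01) {
  req <- c("lon_min", "lon_max", "lat_min", "lat_max")
  assert_that_(all(req %in% names(bbox)),
               "bbox must be named with lon_min, lon_max, lat_min, lat_max")
  assert_that_(cell_size_deg > 0, "cell_size_deg must be > 0")
  assert_that_(bbox[["lon_max"]] > bbox[["lon_min"]] &&
                 bbox[["lat_max"]] > bbox[["lat_min"]],
               "inverted or degenerate bbox")
  n_cols <- ceiling((bbox[["lon_max"]] - bbox[["lon_min"]]) / cell_size_deg - 1e-9)
  n_rows <- ceiling((bbox[["lat_max"]] - bbox[["lat_min"]]) / cell_size_deg - 1e-9)
  ij <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  cells <- tibble::tibble(
    cell_id = seq_len(nrow(ij)),
    row = ij$row,
    col = ij$col,
    centroid_lat = bbox[["lat_min"]] + (ij$row - 0.5) * cell_size_deg,
    centroid_lon = bbox[["lon_min"]] + (ij$col - 0.5) * cell_size_deg
  )
  attr(cells, "grid_spec") <- list(
    origin_lon = unname(bbox[["lon_min"]]),
    origin_lat = unname(bbox[["lat_min"]]),
    cell_size_deg = cell_size_deg,
    n_rows = n_rows, n_cols = n_cols
  )
  cells
}

#' @noRd
grid_spec_of <- function(cells, cell_size_deg = NULL) {
  spec <- attr(cells, "grid_spec")
  if (!is.null(spec)) return(spec)
  assert_that_(!is.null(cell_size_deg),
               "cells carry no grid_spec attribute; supply cell_size_deg")
  list(
    origin_lon = min(cells$centroid_lon) - cell_size_deg / 2,
    origin_lat = min(cells$centroid_lat) - cell_size_deg / 2,
    cell_size_deg = cell_size_deg,
    n_rows = max(cells$row), n_cols = max(cells$col)
  )
}

#' Map points to grid cells by the half-open cell rule
#'
#' @param points data frame with `lat`, `lon`.
#' @param cells grid tibble from [build_grid()].
#' @param cell_size_deg needed only when `cells` lost its `grid_spec`
#'   attribute (e.g. after subsetting).
#' @return integer vector of `cell_id`s, `NA` for points outside the grid (or
#'   in cells that were dropped from `cells`).
#' @export
locate_cells <- function(points, cells, cell_size_deg = NULL) {
  check_lonlat(points)
  spec <- grid_spec_of(cells, cell_size_deg)
  col <- floor((points$lon - spec$origin_lon) / spec$cell_size_deg) + 1
  row <- floor((points$lat - spec$origin_lat) / spec$cell_size_deg) + 1
  key <- ifelse(col >= 1 & row >= 1, paste(row, col), NA)
  cell_key <- paste(cells$row, cells$col)
  cells$cell_id[match(key, cell_key)]
}

#' Assign each grid cell to the municipality containing its centroid
#'
#' @param cells grid tibble from [build_grid()].
#' @param region a region as returned by [read_region_geojson()] or
#'   [generate_region()]: a list with `municipalities` (tibble with
#'   `municipality_id`) and `polygons` (parallel list of multipolygons).
#' @return `cells` with a `municipality_id` column; `NA` for centroids outside
#'   all polygons (such cells are excluded from modelling downstream). Errors
#'   if overlapping polygons claim the same centroid.
#' @export
assign_municipality <- function(cells, region) {
  ids <- region$municipalities$municipality_id
  hit <- matrix(FALSE, nrow(cells), length(ids))
  for (k in seq_along(ids)) {
    hit[, k] <- point_in_multipolygon(cells$centroid_lon, cells$centroid_lat,
                                      region$polygons[[k]])
  }
  n_hit <- rowSums(hit)
  if (any(n_hit > 1)) {
    bad <- which(n_hit > 1)[1]
    offenders <- ids[hit[bad, ]]
    stop(sprintf(
      "overlapping municipality polygons: centroid of cell %d lies in municipalities %s",
      cells$cell_id[bad], paste(offenders, collapse = ", ")), call. = FALSE)
  }
  midx <- apply(hit, 1, function(h) if (any(h)) which(h)[1] else NA_integer_)
  out <- cells
  out$municipality_id <- ids[midx]
  attr(out, "grid_spec") <- attr(cells, "grid_spec")
  out
}

#' Disaggregate municipality covariates onto grid cells
#'
#' Each assigned cell receives the covariate values of its municipality
#' divided by that municipality's number of cells, so that the per-covariate
#' sum over a municipality's cells reproduces the municipality value.
#'
#' @param cells grid tibble with `municipality_id` (see
#'   [assign_municipality()]).
#' @param covariates data frame with `municipality_id` plus numeric covariate
#'   columns.
#' @return `cells` with the covariate columns appended (NA for unassigned
#'   cells) and an `n_cells_municipality` column.
#' @export
disaggregate_covariates <- function(cells, covariates) {
  assert_that_("municipality_id" %in% names(cells),
               "cells must carry municipality_id; run assign_municipality() first")
  cov_cols <- setdiff(names(covariates), c("municipality_id", "urban_rural"))
  counts <- table(cells$municipality_id)
  n_cells <- as.integer(counts[as.character(cells$municipality_id)])
  midx <- match(cells$municipality_id, covariates$municipality_id)
  assert_that_(all(!is.na(midx) | is.na(cells$municipality_id)),
               "some assigned municipalities are missing from the covariate table")
  out <- cells
  out$n_cells_municipality <- n_cells
  for (v in cov_cols) {
    out[[v]] <- as.numeric(covariates[[v]][midx]) / n_cells
  }
  if ("urban_rural" %in% names(covariates)) {
    out$urban_rural <- covariates$urban_rural[midx]
  }
  attr(out, "grid_spec") <- attr(cells, "grid_spec")
  out
}

#' Count point events per grid cell
#'
#' @param events data frame with `lat`, `lon` (one row per OHCA event).
#' @param cells grid tibble.
#' @param cell_size_deg see [locate_cells()].
#' @return `cells` with a `y` column of counts. Events falling outside the
#'   grid are not silently dropped: their number is attached as the
#'   `n_outside` attribute and reported with a message.
#' @export
count_events <- function(events, cells, cell_size_deg = NULL) {
  ids <- locate_cells(events, cells, cell_size_deg)
  n_outside <- sum(is.na(ids))
  if (n_outside > 0) {
    message(sprintf("count_events: %d event(s) fall outside the grid", n_outside))
  }
  tab <- table(factor(ids, levels = cells$cell_id))
  out <- cells
  out$y <- as.integer(tab)
  attr(out, "grid_spec") <- attr(cells, "grid_spec")
  attr(out, "n_outside") <- n_outside
  out
}

#' Lattice adjacency (rook or queen contiguity)
#'
#' Neighbour lists over the cells present in `cells` (dropped cells, e.g.
#' outside the study region, are not neighbours of anyone).
#'
#' @param cells grid tibble with `cell_id`, `row`, `col`.
#' @param contiguity `"rook"` (4 neighbours, default) or `"queen"` (8).
#' @return named list, one integer vector of neighbouring `cell_id`s per cell.
#' @export
build_adjacency <- function(cells, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  offsets <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (contiguity == "queen") {
    offsets <- c(offsets, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  key <- paste(cells$row, cells$col)
  adj <- lapply(seq_len(nrow(cells)), function(i) {
    nb <- vapply(offsets, function(o) {
      match(paste(cells$row[i] + o[1], cells$col[i] + o[2]), key)
    }, integer(1))
    sort(cells$cell_id[nb[!is.na(nb)]])
  })
  names(adj) <- as.character(cells$cell_id)
  adj
}

#' Adjacency as an edge list of positional indices
#' @noRd
adjacency_edges <- function(adjacency, cell_ids = names(adjacency)) {
  cell_ids <- as.character(cell_ids)
  pos <- stats::setNames(seq_along(cell_ids), cell_ids)
  edges <- do.call(rbind, lapply(seq_along(adjacency), function(i) {
    js <- pos[as.character(adjacency[[i]])]
    js <- js[!is.na(js)]
    i0 <- pos[[names(adjacency)[i]]]
    if (length(js) == 0) return(NULL)
    cbind(i0, js)
  }))
  if (is.null(edges)) return(matrix(integer(0), 0, 2))
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  unname(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

#' Connected components of an adjacency structure (BFS)
#' @noRd
adjacency_components <- function(adjacency) {
  n <- length(adjacency)
  ids <- names(adjacency)
  pos <- stats::setNames(seq_len(n), ids)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      i <- queue[[1]]
      queue <- queue[-1]
      nb <- pos[as.character(adjacency[[i]])]
      nb <- nb[!is.na(nb)]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}
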