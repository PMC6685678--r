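#' Configuration for a synthetic study region
#'
#' Describes a rectangular lattice of grid cells partitioned into contiguous
#' municipalities. Defaults give a 20 x 20 lattice (400 cells of 0.01 degrees,
#' ~1.1 km) split into 40 municipalities — a desk-scale version of a cantonal
#' case study (some 3,200 cells over 115 municipalities) preserving its ~10
#' cells-per-municipality resolution.
#'
#' @param lattice_rows,lattice_cols lattice dimensions.
#' @param cell_size_deg cell edge length in degrees.
#' @param n_municipalities number of contiguous municipalities to carve out.
#' @param origin_lat,origin_lon south-west corner of the lattice (degrees).
#' @param seed integer RNG seed.
#' @return a list of class `synthetic_region_config`.
#' @export
synthetic_region_config <- function(lattice_rows = 20, lattice_cols = 20,
                                    cell_size_deg = 0.01,
                                    n_municipalities = 40,
                                    origin_lat = 46.0, origin_lon = 8.7,
                                    seed = 1) {
  assert_that_(cell_size_deg > 0, "cell_size_deg must be > 0")
  assert_that_(n_municipalities >= 1, "need at least one municipality")
  assert_that_(lattice_rows * lattice_cols >= n_municipalities,
               "invalid config: more municipalities than grid cells")
  structure(list(
    lattice_rows = as.integer(lattice_rows),
    lattice_cols = as.integer(lattice_cols),
    cell_size_deg = cell_size_deg,
    n_municipalities = as.integer(n_municipalities),
    origin_lat = origin_lat, origin_lon = origin_lon,
    seed = as.integer(seed)
  ), class = "synthetic_region_config")
}

#' Generate a synthetic region: lattice plus contiguous municipalities
#'
#' Municipalities are grown by seeded region-growing on the lattice: one seed
#' cell per municipality, then repeated random frontier expansion until every
#' cell is claimed. This guarantees a contiguous partition (every cell in
#' exactly one municipality) and is fully reproducible from the seed.
#'
#' @param config a [synthetic_region_config()].
#' @return a list of class `aed_region` with elements `cells` (grid tibble
#'   with `municipality_id`), `municipalities` (tibble with `municipality_id`,
#'   `n_cells`), `polygons` (multipolygon per municipality, unions of cell
#'   squares), and `config`.
#' @export
generate_region <- function(config) {
  stopifnot(inherits(config, "synthetic_region_config"))
  bbox <- c(
    lon_min = config$origin_lon,
    lon_max = config$origin_lon + config$lattice_cols * config$cell_size_deg,
    lat_min = config$origin_lat,
    lat_max = config$origin_lat + config$lattice_rows * config$cell_size_deg
  )
  cells <- build_grid(bbox, config$cell_size_deg)
  n <- nrow(cells)
  k <- config$n_municipalities
  adj <- build_adjacency(cells, "rook")
  pos <- stats::setNames(seq_len(n), names(adj))

  assignment <- with_seed_(config$seed, {
    assign <- rep(NA_integer_, n)
    seeds <- sample.int(n, k)
    assign[seeds] <- seq_len(k)
    # per-municipality frontier: unassigned neighbours of claimed cells
    frontier <- lapply(seeds, function(s) {
      nb <- pos[as.character(adj[[s]])]
      nb[is.na(assign[nb])]
    })
    # round-robin growth: each round every municipality claims one frontier
    # cell (random order, random cell), so sizes stay comparable — real
    # administrative units are not single grid cells
    n_left <- n - k
    while (n_left > 0) {
      progressed <- FALSE
      for (m in sample.int(k)) {
        f <- frontier[[m]]
        f <- f[is.na(assign[f])]
        if (length(f) == 0) {
          frontier[[m]] <- integer(0)
          next
        }
        cell <- if (length(f) == 1) f else sample(f, 1)
        assign[cell] <- m
        n_left <- n_left - 1
        nb <- pos[as.character(adj[[cell]])]
        frontier[[m]] <- unique(c(f[f != cell], nb[is.na(assign[nb])]))
        progressed <- TRUE
        if (n_left == 0) break
      }
      if (!progressed) break # unreachable on a connected lattice
    }
    assign
  })

  cells$municipality_id <- assignment
  municipalities <- tibble::tibble(
    municipality_id = seq_len(k),
    n_cells = as.integer(table(factor(assignment, levels = seq_len(k))))
  )
  half <- config$cell_size_deg / 2
  polygons <- lapply(seq_len(k), function(m) {
    idx <- which(assignment == m)
    lapply(idx, function(i) {
      cx <- cells$centroid_lon[i]
      cy <- cells$centroid_lat[i]
      list(cbind(
        lon = c(cx - half, cx + half, cx + half, cx - half, cx - half),
        lat = c(cy - half, cy - half, cy + half, cy + half, cy - half)
      ))
    })
  })
  names(polygons) <- as.character(municipalities$municipality_id)
  structure(list(cells = cells, municipalities = municipalities,
                 polygons = polygons, config = config),
            class = "aed_region")
}

#' Generate synthetic municipality covariates
#'
#' One row per municipality with the covariate roster used in the OHCA model:
#' population density, proportion male, proportion aged over 65, financial
#' strength, and hectares of land used for transport, industry/commerce,
#' buildings, recreation and special urban use. Proportions are drawn from
#' Beta distributions, land-use hectares as a Dirichlet split of each
#' municipality's settlement area, and the positive indices from log-normals;
#' these distributional stand-ins respect the ranges of the real covariates
#' without claiming to be calibrated to any region.
#'
#' A synthetic `urban_rural` label (an input attribute downstream, not a
#' classification rule) marks municipalities with population density above
#' 300 per km2 as urban.
#'
#' @param municipalities tibble with `municipality_id` and `n_cells` (e.g.
#'   from [generate_region()]), or an `aed_region`.
#' @param seed integer RNG seed.
#' @return tibble with `municipality_id`, `urban_rural` and 9 numeric
#'   covariate columns.
#' @export
generate_covariates <- function(municipalities, seed = 1) {
  if (inherits(municipalities, "aed_region")) {
    municipalities <- municipalities$municipalities
  }
  k <- nrow(municipalities)
  assert_that_(k >= 1, "need at least one municipality")
  with_seed_({
    seed
  }, {
    area_km2 <- pmax(municipalities$n_cells, 1) * 1.21 # 1.1 km x 1.1 km cells
    area_ha <- area_km2 * 100
    pop_density <- stats::rlnorm(k, log(150), 0.7)
    prop_male <- stats::rbeta(k, 0.49 * 300, 0.51 * 300)
    prop_over_65 <- stats::rbeta(k, 0.20 * 120, 0.80 * 120)
    financial_strength <- stats::rlnorm(k, log(80), 0.35)
    settlement <- stats::rbeta(k, 2, 6) * area_ha
    # Dirichlet split of settlement hectares across the five land uses
    alpha <- c(transport = 3, industry = 2, buildings = 4,
               recreation = 1.5, urban = 1)
    gam <- matrix(stats::rgamma(k * 5, shape = rep(alpha, each = k)), k, 5)
    shares <- gam / rowSums(gam)
    tibble::tibble(
      municipality_id = municipalities$municipality_id,
      pop_density = pop_density,
      prop_male = prop_male,
      prop_over_65 = prop_over_65,
      financial_strength = financial_strength,
      ha_transport = shares[, 1] * settlement,
      ha_industry = shares[, 2] * settlement,
      ha_buildings = shares[, 3] * settlement,
      ha_recreation = shares[, 4] * settlement,
      ha_urban = shares[, 5] * settlement,
      urban_rural = ifelse(pop_density > 300, "urban", "rural")
    )
  })
}

#' Sample an intrinsic CAR (ICAR) field
#'
#' Draws one realisation of the intrinsic conditional autoregressive
#' distribution with precision matrix `tau_u * (D - W)` subject to the
#' sum-to-zero constraint, via eigendecomposition of the (rank-deficient)
#' structure matrix with the null eigenvector dropped. Exact at desk scale.
#'
#' @param adjacency named neighbour list as from [build_adjacency()];
#'   must describe a connected graph.
#' @param tau_u ICAR precision (> 0).
#' @param seed integer RNG seed.
#' @param n_draws number of independent fields to draw.
#' @return numeric vector of length `length(adjacency)` (or a matrix with
#'   `n_draws` rows), each draw summing to zero to numerical tolerance.
#' @export
simulate_icar_field <- function(adjacency, tau_u, seed = 1, n_draws = 1) {
  assert_that_(tau_u > 0, "tau_u must be > 0")
  comp <- adjacency_components(adjacency)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop(sprintf("adjacency graph is disconnected: %d components (sizes %s)",
                 max(comp), paste(sizes, collapse = ", ")), call. = FALSE)
  }
  n <- length(adjacency)
  edges <- adjacency_edges(adjacency)
  W <- matrix(0, n, n)
  W[edges] <- 1
  W[edges[, 2:1, drop = FALSE]] <- 1
  Q <- diag(rowSums(W)) - W
  eig <- eigen(Q, symmetric = TRUE)
  keep <- seq_len(n - 1) # connected graph: exactly one null eigenvalue
  sd_k <- 1 / sqrt(tau_u * eig$values[keep])
  u <- with_seed_(seed, {
    z <- matrix(stats::rnorm(n_draws * (n - 1)), n - 1, n_draws)
    t(eig$vectors[, keep, drop = FALSE] %*% (z * sd_k))
  })
  u <- u - rowMeans(u) # eigenvectors are orthogonal to 1; this is a no-op up to rounding
  if (n_draws == 1) drop(u) else u
}

#' Generative parameters for the zero-inflated Poisson OHCA model
#'
#' Defaults emulate the case-study conditions at desk scale: a high share of
#' zero-count cells (around 85%) arising from both structural zeros and low
#' Poisson rates, covariate effects of moderate size on the log scale, and a
#' spatially structured field comparable in magnitude to the unstructured
#' noise. `beta` is named; names select the covariate columns used.
#'
#' @param beta0 intercept of the log-rate.
#' @param beta named vector of covariate coefficients (log scale).
#' @param tau_u ICAR precision (> 0).
#' @param sigma_v standard deviation of the unstructured effect (>= 0).
#' @param p_zero structural-zero probability in `[0, 1]`.
#' @param n_aeds,n_buildings numbers of existing AEDs and candidate buildings
#'   scattered uniformly over the region.
#' @return a list of class `generative_params`.
#' @export
generative_params <- function(beta0 = -0.4,
                              beta = c(pop_density = 0.0015,
                                       prop_male = 8,
                                       prop_over_65 = 15,
                                       financial_strength = -0.03,
                                       ha_transport = 0.03,
                                       ha_industry = 0.025,
                                       ha_buildings = -0.02,
                                       ha_recreation = 0.06,
                                       ha_urban = -0.05),
                              tau_u = 8, sigma_v = 0.2, p_zero = 0.7,
                              n_aeds = 90, n_buildings = 1500) {
  assert_that_(tau_u > 0, "tau_u must be > 0")
  assert_that_(sigma_v >= 0, "sigma_v must be >= 0")
  assert_that_(p_zero >= 0 && p_zero <= 1, "p_zero must lie in [0, 1]")
  assert_that_(!is.null(names(beta)) || length(beta) == 0,
               "beta must be a named vector")
  structure(list(beta0 = beta0, beta = beta, tau_u = tau_u, sigma_v = sigma_v,
                 p_zero = p_zero, n_aeds = as.integer(n_aeds),
                 n_buildings = as.integer(n_buildings)),
            class = "generative_params")
}

#' Simulate OHCA counts, event points, AEDs and candidate buildings
#'
#' Counts follow the zero-inflated Poisson mixture: with probability `p_zero`
#' a cell's count is a structural zero, otherwise Poisson with rate
#' `exp(beta0 + x %*% beta + u + v)` where `u` is an ICAR field and `v` iid
#' Gaussian noise. Event coordinates are uniform within their cell; AED and
#' building coordinates are uniform over the region's bounding box.
#'
#' @param cells grid tibble with covariate columns named as in
#'   `params$beta` (e.g. from [disaggregate_covariates()]).
#' @param params a [generative_params()].
#' @param seed integer RNG seed.
#' @param adjacency optional neighbour list (rook contiguity of `cells` by
#'   default).
#' @param cell_size_deg see [locate_cells()].
#' @return list with `cells` (input plus `y`), `events`, `aeds`, `buildings`
#'   (point tibbles) and `truth` (u, v, lambda, structural-zero indicator and
#'   the parameters), for parameter-recovery studies.
#' @export
simulate_ohca_data <- function(cells, params, seed = 1, adjacency = NULL,
                               cell_size_deg = NULL) {
  stopifnot(inherits(params, "generative_params"))
  vars <- names(params$beta)
  assert_that_(all(vars %in% names(cells)),
               sprintf("cells lack covariate column(s): %s",
                       paste(setdiff(vars, names(cells)), collapse = ", ")))
  spec <- grid_spec_of(cells, cell_size_deg)
  n <- nrow(cells)
  if (is.null(adjacency)) adjacency <- build_adjacency(cells, "rook")
  X <- as.matrix(cells[, vars, drop = FALSE])
  u <- if (length(adjacency) > 1 && is.finite(params$tau_u)) {
    simulate_icar_field(adjacency, params$tau_u, seed = seed + 1L)
  } else {
    rep(0, n) # infinite precision: the spatial field is exactly zero
  }
  out <- with_seed_(seed, {
    v <- stats::rnorm(n, 0, params$sigma_v)
    lambda <- build_linear_predictor(X, params$beta0, params$beta, u, v)
    z <- stats::rbinom(n, 1, params$p_zero)
    y <- ifelse(z == 1, 0L, stats::rpois(n, lambda))
    # event points: uniform within their cell
    idx <- rep(seq_len(n), y)
    half <- spec$cell_size_deg / 2
    events <- tibble::tibble(
      event_id = seq_along(idx),
      lat = cells$centroid_lat[idx] + stats::runif(length(idx), -half, half),
      lon = cells$centroid_lon[idx] + stats::runif(length(idx), -half, half)
    )
    bbox_lon <- c(spec$origin_lon, spec$origin_lon + spec$n_cols * spec$cell_size_deg)
    bbox_lat <- c(spec$origin_lat, spec$origin_lat + spec$n_rows * spec$cell_size_deg)
    aeds <- tibble::tibble(
      aed_id = seq_len(params$n_aeds),
      lat = stats::runif(params$n_aeds, bbox_lat[1], bbox_lat[2]),
      lon = stats::runif(params$n_aeds, bbox_lon[1], bbox_lon[2]),
      availability = sample(c("public_24_7", "time_limited"),
                            params$n_aeds, replace = TRUE, prob = c(0.6, 0.4)),
      supply = 1
    )
    buildings <- tibble::tibble(
      site_id = seq_len(params$n_buildings),
      lat = stats::runif(params$n_buildings, bbox_lat[1], bbox_lat[2]),
      lon = stats::runif(params$n_buildings, bbox_lon[1], bbox_lon[2])
    )
    list(y = as.integer(y), v = v, lambda = lambda, z = z,
         events = events, aeds = aeds, buildings = buildings)
  })
  cells_out <- cells
  cells_out$y <- out$y
  attr(cells_out, "grid_spec") <- spec
  list(
    cells = cells_out,
    events = out$events,
    aeds = out$aeds,
    buildings = out$buildings,
    truth = list(u = u, v = out$v, lambda = out$lambda, z = out$z,
                 params = params)
  )
}

#' Simulate a complete synthetic study bundle
#'
#' Convenience wrapper: region, covariates, disaggregation, counts, points.
#'
#' @param config a [synthetic_region_config()].
#' @param params a [generative_params()].
#' @return the [simulate_ohca_data()] bundle plus `region`, `covariates` and
#'   `adjacency` entries.
#' @export
simulate_study <- function(config = synthetic_region_config(),
                           params = generative_params()) {
  region <- generate_region(config)
  covariates <- generate_covariates(region, seed = config$seed + 1L)
  cells <- disaggregate_covariates(region$cells, covariates)
  adjacency <- build_adjacency(cells, "rook")
  sim <- simulate_ohca_data(cells, params, seed = config$seed + 2L,
                            adjacency = adjacency)
  c(sim, list(region = region, covariates = covariates, adjacency = adjacency))
}

#' Write a synthetic bundle to disk (GeoJSON + CSV)
#'
#' Emits `region.geojson`, `covariates.csv`, `events.csv`, `aeds.csv`,
#' `buildings.csv` in `dir` — the input formats consumed by [run_pipeline()].
#'
#' @param bundle output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_region_geojson(bundle$region$municipalities, bundle$region$polygons,
                       file.path(dir, "region.geojson"))
  utils::write.csv(bundle$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$aeds, file.path(dir, "aeds.csv"), row.names = FALSE)
  utils::write.csv(bundle$buildings, file.path(dir, "buildings.csv"),
                   row.names = FALSE)
  invisible(dir)
}
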