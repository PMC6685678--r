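#' Configuration for the end-to-end analysis pipeline
#'
#' Paths to the five inputs plus every tunable of the stages, pre-filled with
#' the study defaults: 0.01-degree cells, 100 m catchment and coverage radius,
#' budget of 100 new AEDs, predicted-count threshold 1, rook contiguity.
#'
#' @param region,events,covariates,aeds,buildings input paths (GeoJSON for
#'   the region, CSV for the rest).
#' @param out_dir output directory for the run.
#' @param cell_size_deg grid resolution in degrees.
#' @param d0 catchment radius (metres) of the access model.
#' @param kernel decay kind, `"exponential"` or `"stepwise"`.
#' @param coverage_radius coverage radius (metres) of the optimiser.
#' @param n_new_aeds budget N of the maximal covering problem.
#' @param threshold predicted-count threshold of the priority ranking.
#' @param top_k rows of the evaluation tables.
#' @param contiguity `"rook"` or `"queen"`.
#' @param sampler_seed,permutation_seed seeds for the MCMC fit and the
#'   Moran's I permutation test.
#' @param n_iter,n_burn,thin MCMC controls passed to [fit_zip_car()].
#' @param node_limit branch-and-bound node budget of [solve_mclp()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(region, events, covariates, aeds, buildings,
                            out_dir,
                            cell_size_deg = 0.01, d0 = 100,
                            kernel = c("exponential", "stepwise"),
                            coverage_radius = 100, n_new_aeds = 100,
                            threshold = 1, top_k = 20,
                            contiguity = c("rook", "queen"),
                            sampler_seed = 1, permutation_seed = 1,
                            n_iter = 6000, n_burn = 2000, thin = 2,
                            node_limit = 2e5) {
  kernel <- match.arg(kernel)
  contiguity <- match.arg(contiguity)
  assert_that_(cell_size_deg > 0 && d0 > 0 && coverage_radius > 0 &&
                 n_new_aeds >= 0 && top_k >= 1,
               "numeric pipeline parameters must be positive")
  structure(list(
    paths = list(region = region, events = events, covariates = covariates,
                 aeds = aeds, buildings = buildings, out_dir = out_dir),
    cell_size_deg = cell_size_deg, d0 = d0, kernel = kernel,
    coverage_radius = coverage_radius, n_new_aeds = n_new_aeds,
    threshold = threshold, top_k = top_k, contiguity = contiguity,
    sampler_seed = sampler_seed, permutation_seed = permutation_seed,
    n_iter = n_iter, n_burn = n_burn, thin = thin, node_limit = node_limit
  ), class = "pipeline_config")
}

#' @noRd
stage_error <- function(stage, msg) {
  stop(structure(
    class = c("pipeline_stage_error", "error", "condition"),
    list(message = sprintf("[stage %s] %s", stage, msg), call = NULL,
         stage = stage)
  ))
}

#' @noRd
require_file <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    stage_error(stage, sprintf("input file not found: %s", path %||% "<missing>"))
  }
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: gridding (grid, municipality assignment, covariate
#' disaggregation, event counts, adjacency), the zero-inflated Poisson CAR
#' fit, floating-catchment access scores, maximal-covering placement of new
#' AED sites, and the priority-ranking evaluation. All stage outputs plus a
#' manifest (configuration, seeds, package version, per-stage row counts, no
#' timestamps) are written to `config$paths$out_dir`; identical configuration
#' and seeds give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return (invisibly) a list with the in-memory stage results: `cells`,
#'   `fit`, `access`, `solution`, `tables`, `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- stage: read ----
  region <- tryCatch(
    read_region_geojson(require_file(config$paths$region, "read")),
    error = function(e) stage_error("read", conditionMessage(e)))
  events <- utils::read.csv(require_file(config$paths$events, "read"))
  covariates <- utils::read.csv(require_file(config$paths$covariates, "read"))
  aeds <- utils::read.csv(require_file(config$paths$aeds, "access"))
  buildings <- utils::read.csv(require_file(config$paths$buildings, "optimize"))
  say("read: %d events, %d AEDs, %d candidate buildings, %d municipalities",
      nrow(events), nrow(aeds), nrow(buildings), nrow(region$municipalities))

  ## ---- stage: grid ----
  cells <- tryCatch({
    rings <- unlist(lapply(region$polygons,
                           function(mp) unlist(mp, recursive = FALSE)),
                    recursive = FALSE)
    lons <- unlist(lapply(rings, function(r) r[, 1]))
    lats <- unlist(lapply(rings, function(r) r[, 2]))
    bbox <- c(lon_min = min(lons), lon_max = max(lons),
              lat_min = min(lats), lat_max = max(lats))
    g <- build_grid(bbox, config$cell_size_deg)
    g <- assign_municipality(g, region)
    g <- disaggregate_covariates(g, covariates)
    count_events(events, g)
  }, error = function(e) stage_error("grid", conditionMessage(e)))
  cells_model <- cells[!is.na(cells$municipality_id), , drop = FALSE]
  attr(cells_model, "grid_spec") <- attr(cells, "grid_spec")
  adjacency <- build_adjacency(cells_model, config$contiguity)
  utils::write.csv(cells_model, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  say("grid: %d cells (%d in a municipality), %d events on grid",
      nrow(cells), nrow(cells_model), sum(cells$y))

  ## ---- stage: fit ----
  fit <- tryCatch(
    fit_zip_car(cells_model, adjacency,
                n_iter = config$n_iter, n_burn = config$n_burn,
                thin = config$thin, seed = config$sampler_seed),
    error = function(e) stage_error("fit", conditionMessage(e)))
  mi <- morans_i(fit$cells$residual, adjacency,
                 seed = config$permutation_seed)
  utils::write.csv(fit$cells, file.path(out_dir, "posterior_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$coef_table, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(rhat = as.list(fit$rhat), converged = fit$converged,
         morans_i = mi$I, morans_p = mi$p_value,
         posterior_mean_p = mean(fit$draws$p)),
    file.path(out_dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  say("fit: max R-hat %.3f, Moran's I %.3f (p = %.3f)",
      max(fit$rhat), mi$I, mi$p_value)

  ## ---- stage: access ----
  acc <- tryCatch({
    cells_pred <- cells_model
    cells_pred$pred_mean <- fit$cells$pred_mean
    attr(cells_pred, "grid_spec") <- attr(cells, "grid_spec")
    compute_access(aeds, cells_pred, "pred_mean",
                   decay_config(config$d0, config$kernel))
  }, error = function(e) stage_error("access", conditionMessage(e)))
  utils::write.csv(acc$ratios, file.path(out_dir, "aed_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(
    acc$cells[, c("cell_id", "centroid_lat", "centroid_lon", "pred_mean",
                  "access")],
    file.path(out_dir, "access.csv"), row.names = FALSE)
  say("access: %d/%d AEDs with zero decayed demand",
      length(acc$zero_demand_aeds), nrow(aeds))

  ## ---- stage: optimize ----
  sol <- tryCatch({
    uncovered <- remove_covered(events, aeds, config$coverage_radius)
    problem <- make_coverage_problem(uncovered, buildings,
                                     config$coverage_radius,
                                     config$n_new_aeds)
    list(solution = solve_mclp(problem, config$node_limit),
         n_removed = attr(uncovered, "n_removed"),
         n_uncovered = nrow(uncovered))
  }, error = function(e) stage_error("optimize", conditionMessage(e)))
  solution <- sol$solution
  sel <- buildings[as.character(buildings$site_id %||% seq_len(nrow(buildings)))
                   %in% solution$selected, , drop = FALSE]
  utils::write.csv(sel, file.path(out_dir, "selected_sites.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_ohca = nrow(events), n_removed_covered = sol$n_removed,
         n_uncovered = sol$n_uncovered, budget = solution$N,
         objective = solution$objective, optimal = solution$optimal,
         method = solution$method),
    file.path(out_dir, "coverage_report.json"), auto_unbox = TRUE, digits = NA)
  say("optimize: %d of %d uncovered OHCAs newly covered (%s)",
      solution$objective, sol$n_uncovered, solution$method)

  ## ---- stage: rank ----
  tables <- tryCatch({
    ranked <- priority_rank(acc$cells, threshold = config$threshold)
    counts <- count_new_aeds(solution, buildings, cells_model)
    evaluation_tables(ranked, counts, config$top_k)
  }, error = function(e) stage_error("rank", conditionMessage(e)))
  utils::write.csv(tables$by_priority,
                   file.path(out_dir, "priority_table.csv"), row.names = FALSE)
  utils::write.csv(tables$by_aeds_added,
                   file.path(out_dir, "aeds_added_table.csv"),
                   row.names = FALSE)
  map_cells <- acc$cells
  map_cells$n_aeds_added <- count_new_aeds(solution, buildings,
                                           cells_model)$n_aeds_added
  write_cells_geojson(map_cells, config$cell_size_deg,
                      file.path(out_dir, "cells_map.geojson"))

  ## ---- manifest ----
  manifest <- list(
    package_version = as.character(utils::packageVersion("aedaccess")),
    config = config[setdiff(names(config), "paths")],
    paths = config$paths,
    rows = list(events = nrow(events), aeds = nrow(aeds),
                buildings = nrow(buildings),
                cells = nrow(cells), cells_model = nrow(cells_model),
                ranked = nrow(tables$by_priority)),
    outputs = c("cells.csv", "posterior_cells.csv", "coefficients.csv",
                "diagnostics.json", "aed_ratios.csv", "access.csv",
                "selected_sites.csv", "coverage_report.json",
                "priority_table.csv", "aeds_added_table.csv",
                "cells_map.geojson")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: outputs in %s", out_dir)
  invisible(list(cells = cells_model, fit = fit, access = acc,
                 solution = solution, tables = tables, manifest = manifest))
}

#' Validate pipeline input files
#'
#' Report-only checks: does each file parse, how many rows, how many
#' coordinate-range violations, how many duplicated ids.
#'
#' @param paths named list/vector of file paths (any of `region`, `events`,
#'   `covariates`, `aeds`, `buildings`).
#' @return tibble with one row per file: `input`, `path`, `status`, `n_rows`,
#'   `n_bad_coords`, `n_duplicate_ids`, `detail`.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  id_cols <- c(events = "event_id", aeds = "aed_id", buildings = "site_id",
               covariates = "municipality_id")
  rows <- lapply(names(paths), function(nm) {
    path <- paths[[nm]]
    row <- tibble::tibble(input = nm, path = path, status = "ok",
                          n_rows = NA_integer_, n_bad_coords = NA_integer_,
                          n_duplicate_ids = NA_integer_, detail = "")
    if (!file.exists(path)) {
      row$status <- "missing"
      return(row)
    }
    parsed <- tryCatch({
      if (grepl("\\.geojson$|\\.json$", path)) {
        rg <- read_region_geojson(path)
        list(df = rg$municipalities, geo = TRUE)
      } else {
        list(df = utils::read.csv(path), geo = FALSE)
      }
    }, error = function(e) e)
    if (inherits(parsed, "error")) {
      row$status <- "parse_error"
      row$detail <- conditionMessage(parsed)
      return(row)
    }
    df <- parsed$df
    row$n_rows <- nrow(df)
    if (all(c("lat", "lon") %in% names(df))) {
      bad <- !is.finite(df$lat) | df$lat < -90 | df$lat > 90 |
        !is.finite(df$lon) | df$lon < -180 | df$lon > 360
      row$n_bad_coords <- sum(bad)
      if (any(bad)) {
        row$status <- "flagged"
        row$detail <- sprintf("coordinate range violations in rows %s",
                              paste(utils::head(which(bad), 5), collapse = ", "))
      }
    }
    idc <- id_cols[nm]
    if (!is.na(idc) && idc %in% names(df)) {
      ndup <- sum(duplicated(df[[idc]]))
      row$n_duplicate_ids <- ndup
      if (ndup > 0) {
        row$status <- "flagged"
        row$detail <- paste(row$detail,
                            sprintf("%d duplicated %s", ndup, idc))
      }
    }
    row
  })
  dplyr::bind_rows(rows)
}
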