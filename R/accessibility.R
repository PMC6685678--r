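#' Distance-decay configuration for the floating catchment
#'
#' The exponential kind is the truncated Gaussian kernel
#' `G(d, d0) = (exp(-(d/d0)^2 / 2) - exp(-1/2)) / (1 - exp(-1/2))` for
#' `d <= d0` and 0 beyond: it equals 1 at `d = 0`, decreases strictly, and
#' reaches 0 continuously at the catchment radius `d0`. The stepwise kind is
#' piecewise constant on the radii in `step_breaks` (default: a single step of
#' weight 1 up to `d0`).
#'
#' @param d0 catchment radius in metres (default 100; 250 is a supported
#'   sensitivity value).
#' @param kind `"exponential"` (default) or `"stepwise"`.
#' @param step_breaks for the stepwise kind: data frame with `radius`
#'   (metres, increasing) and `weight` (nonincreasing, in `[0, 1]`); a
#'   distance `d` gets the weight of the first break with `d <= radius`.
#' @return list of class `decay_config`.
#' @export
decay_config <- function(d0 = 100, kind = c("exponential", "stepwise"),
                         step_breaks = NULL) {
  kind <- match.arg(kind)
  assert_that_(d0 > 0, "d0 must be > 0")
  if (kind == "stepwise") {
    if (is.null(step_breaks)) {
      step_breaks <- data.frame(radius = d0, weight = 1)
    }
    assert_that_(all(diff(step_breaks$radius) > 0),
                 "step_breaks radii must be increasing")
    assert_that_(all(step_breaks$weight >= 0 & step_breaks$weight <= 1),
                 "step weights must lie in [0, 1]")
    assert_that_(all(diff(step_breaks$weight) <= 0),
                 "step weights must be nonincreasing in radius")
    assert_that_(max(step_breaks$radius) <= d0 + 1e-9,
                 "step_breaks must not extend beyond d0")
  }
  structure(list(d0 = d0, kind = kind, step_breaks = step_breaks),
            class = "decay_config")
}

#' Distance-decay weight
#'
#' @param d distances in metres (vectorised, >= 0).
#' @param config a [decay_config()].
#' @return weights in `[0, 1]`; 0 beyond the catchment radius.
#' @examples
#' decay_weight(c(0, 50, 100, 150), decay_config(d0 = 100))
#' @export
decay_weight <- function(d, config = decay_config()) {
  assert_that_(all(d >= 0), "distances must be nonnegative")
  if (config$kind == "exponential") {
    g <- (exp(-0.5 * (d / config$d0)^2) - exp(-0.5)) / (1 - exp(-0.5))
    ifelse(d <= config$d0, pmax(0, g), 0)
  } else {
    br <- config$step_breaks
    idx <- findInterval(d, br$radius, left.open = TRUE) + 1L
    w <- c(br$weight, 0)[pmin(idx, nrow(br) + 1L)]
    ifelse(d <= config$d0, w, 0)
  }
}

#' Step 1 of the floating catchment: supply-to-demand ratio per AED
#'
#' `R_j = S_j / sum over demand points within d0 of (D * G(d, d0))`, with
#' great-circle distances from the AED to the demand points (grid-cell
#' centroids carrying the model's predicted counts). An AED with zero decayed
#' demand in its catchment gets `R_j = 0` and is flagged rather than dividing
#' by zero, so that unbounded ratios cannot dominate the access scores; the
#' flags are returned for audit.
#'
#' @param aeds tibble with `aed_id`, `lat`, `lon`, optional `supply`
#'   (default 1) and `availability`.
#' @param demand tibble with `cell_id`, `lat`, `lon`, `demand` (>= 0).
#' @param config a [decay_config()].
#' @param public_only if `TRUE`, AEDs whose `availability` is not
#'   `"public_24_7"` contribute zero supply.
#' @return tibble with `aed_id`, `ratio`, `zero_demand` flag.
#' @export
supply_demand_ratio <- function(aeds, demand, config = decay_config(),
                                public_only = FALSE) {
  check_lonlat(aeds, "aeds")
  check_lonlat(demand, "demand")
  assert_that_(all(demand$demand >= 0), "demand must be nonnegative")
  supply <- aeds[["supply"]] %||% rep(1, nrow(aeds))
  if (public_only && "availability" %in% names(aeds)) {
    supply <- supply * (aeds$availability == "public_24_7")
  }
  d <- haversine_matrix(aeds, demand) # J_aed x n_demand
  w <- matrix(decay_weight(as.vector(d), config), nrow(aeds))
  denom <- drop(w %*% demand$demand)
  zero <- denom <= 0
  tibble::tibble(
    aed_id = aeds$aed_id,
    ratio = ifelse(zero, 0, supply / ifelse(zero, 1, denom)),
    zero_demand = zero
  )
}

#' Step 2 of the floating catchment: access score per grid cell
#'
#' `A_i` is the sum of the supply-to-demand ratios of the AEDs whose
#' coordinates fall inside cell `i`; cells hosting no AED score 0.
#'
#' @param aeds tibble with `aed_id`, `lat`, `lon`.
#' @param ratios output of [supply_demand_ratio()] (matched by `aed_id`).
#' @param cells grid tibble.
#' @param cell_size_deg see [locate_cells()].
#' @return `cells` with an `access` column; AEDs outside the grid are counted
#'   in the `n_outside` attribute.
#' @export
access_scores <- function(aeds, ratios, cells, cell_size_deg = NULL) {
  r <- ratios$ratio[match(aeds$aed_id, ratios$aed_id)]
  assert_that_(!anyNA(r), "every AED needs a ratio (match by aed_id)")
  ids <- locate_cells(aeds, cells, cell_size_deg)
  inside <- !is.na(ids)
  sums <- tapply(r[inside], factor(ids[inside], levels = cells$cell_id), sum)
  out <- cells
  out$access <- as.numeric(ifelse(is.na(sums), 0, sums))
  attr(out, "grid_spec") <- attr(cells, "grid_spec")
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Two-step floating catchment access, end to end
#'
#' @param aeds AED tibble (`aed_id`, `lat`, `lon`, ...).
#' @param cells grid tibble with a demand column.
#' @param demand_col name of the per-cell demand column (the model's
#'   posterior-mean predicted count).
#' @param config a [decay_config()].
#' @param public_only see [supply_demand_ratio()].
#' @param cell_size_deg see [locate_cells()].
#' @return list with `cells` (input plus `access`), `ratios` (per AED) and
#'   `zero_demand_aeds` (flagged AED ids).
#' @export
compute_access <- function(aeds, cells, demand_col = "pred_mean",
                           config = decay_config(), public_only = FALSE,
                           cell_size_deg = NULL) {
  assert_that_(demand_col %in% names(cells),
               sprintf("cells lack demand column '%s'", demand_col))
  demand <- tibble::tibble(
    cell_id = cells$cell_id,
    lat = cells$centroid_lat,
    lon = cells$centroid_lon,
    demand = cells[[demand_col]]
  )
  ratios <- supply_demand_ratio(aeds, demand, config, public_only)
  scored <- access_scores(aeds, ratios, cells, cell_size_deg)
  list(cells = scored, ratios = ratios,
       zero_demand_aeds = ratios$aed_id[ratios$zero_demand])
}
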