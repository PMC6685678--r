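#' Priority ranking of grid cells by access and predicted demand
#'
#' Cells whose predicted OHCA count exceeds `threshold` are ordered by lowest
#' access score first, ties broken by highest predicted count, remaining ties
#' by `cell_id` (full determinism); the rank is the position in that order.
#'
#' @param cells tibble with `cell_id`, an access column and a predicted-count
#'   column (and optionally `urban_rural`).
#' @param access_col,predicted_col column names.
#' @param threshold cells with predicted count <= `threshold` are excluded
#'   (default 1, i.e. only cells where more than one event is expected).
#' @return tibble with `cell_id`, `priority_rank`, `access`, `predicted`
#'   (and `urban_rural` when available), sorted by rank.
#' @export
priority_rank <- function(cells, access_col = "access",
                          predicted_col = "pred_mean", threshold = 1) {
  assert_that_(all(c(access_col, predicted_col, "cell_id") %in% names(cells)),
               "cells must have cell_id, access and predicted columns")
  out <- tibble::tibble(
    cell_id = cells$cell_id,
    access = cells[[access_col]],
    predicted = cells[[predicted_col]]
  )
  if ("urban_rural" %in% names(cells)) out$urban_rural <- cells$urban_rural
  out <- out[out$predicted > threshold, , drop = FALSE]
  ord <- order(out$access, -out$predicted, out$cell_id)
  out <- out[ord, , drop = FALSE]
  out$priority_rank <- seq_len(nrow(out))
  out[, c("cell_id", "priority_rank", "access", "predicted",
          intersect("urban_rural", names(out)))]
}

#' Count newly placed AEDs per grid cell
#'
#' @param solution a `coverage_solution` (see [solve_mclp()]).
#' @param candidates the candidate-site tibble the problem was built from
#'   (`site_id`, `lat`, `lon`).
#' @param cells grid tibble.
#' @param cell_size_deg see [locate_cells()].
#' @return tibble with `cell_id` and `n_aeds_added`; selected sites outside
#'   the grid are counted in the `n_outside` attribute, so that
#'   `sum(n_aeds_added) + n_outside` equals the number of selected sites.
#' @export
count_new_aeds <- function(solution, candidates, cells, cell_size_deg = NULL) {
  stopifnot(inherits(solution, "coverage_solution"))
  if (is.null(candidates$site_id)) candidates$site_id <- seq_len(nrow(candidates))
  sel <- candidates[as.character(candidates$site_id) %in% solution$selected, ,
                    drop = FALSE]
  ids <- locate_cells(sel, cells, cell_size_deg)
  inside <- !is.na(ids)
  tab <- table(factor(ids[inside], levels = cells$cell_id))
  out <- tibble::tibble(cell_id = cells$cell_id,
                        n_aeds_added = as.integer(tab))
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Evaluation tables: priority areas vs AED placements
#'
#' Table A lists the `top_k` highest-priority (least accessible, most demand)
#' cells with the number of AEDs the placement solution put in each — do the
#' placements reach the areas most in need? Table B lists the `top_k` cells
#' receiving the most new AEDs (ties resolved by better priority rank, then
#' `cell_id`), with their priority ranks joined — where does the optimiser
#' concentrate AEDs?
#'
#' @param ranked output of [priority_rank()].
#' @param counts output of [count_new_aeds()].
#' @param top_k rows per table (default 20).
#' @return list with tibbles `by_priority` and `by_aeds_added`.
#' @export
evaluation_tables <- function(ranked, counts, top_k = 20) {
  joined <- dplyr::left_join(ranked, counts, by = "cell_id")
  joined$n_aeds_added[is.na(joined$n_aeds_added)] <- 0L
  if (nrow(joined) < top_k) {
    warning(sprintf("only %d ranked cells available (top_k = %d)",
                    nrow(joined), top_k), call. = FALSE)
  }
  by_priority <- utils::head(joined[order(joined$priority_rank), ], top_k)
  ord_b <- order(-joined$n_aeds_added, joined$priority_rank, joined$cell_id)
  by_aeds <- utils::head(joined[ord_b, ], top_k)
  list(by_priority = by_priority, by_aeds_added = by_aeds)
}
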