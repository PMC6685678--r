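#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed_ <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
assert_that_ <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Check latitude/longitude columns, stopping on out-of-range values
#' @noRd
check_lonlat <- function(df, what = "points") {
  assert_that_(all(c("lat", "lon") %in% names(df)),
               sprintf("%s must have 'lat' and 'lon' columns", what))
  bad_lat <- !is.finite(df$lat) | df$lat < -90 | df$lat > 90
  bad_lon <- !is.finite(df$lon) | df$lon < -180 | df$lon > 360
  if (any(bad_lat) || any(bad_lon)) {
    stop(sprintf("%s: %d row(s) with out-of-range or non-finite coordinates (rows %s)",
                 what, sum(bad_lat | bad_lon),
                 paste(utils::head(which(bad_lat | bad_lon), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}
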