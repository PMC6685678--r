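#' Binary OHCA-by-site coverage matrix
#'
#' `a[j, i] = 1` iff OHCA `j` lies within `radius` metres (great circle,
#' closed boundary: a point at exactly `radius` counts as covered) of
#' candidate site `i`.
#'
#' @param ohcas tibble with `lat`, `lon` (and optionally `event_id`).
#' @param candidates tibble with `lat`, `lon` (and optionally `site_id`).
#' @param radius coverage radius in metres (> 0).
#' @return integer 0/1 matrix with OHCA ids as row names and site ids as
#'   column names.
#' @export
build_coverage_matrix <- function(ohcas, candidates, radius = 100) {
  assert_that_(radius > 0, "radius must be > 0")
  d <- haversine_matrix(ohcas, candidates)
  # closed boundary; the micron slack absorbs floating-point rounding of
  # points constructed to sit exactly at the radius
  a <- matrix(as.integer(d <= radius + 1e-6), nrow(ohcas), nrow(candidates))
  rownames(a) <- as.character(ohcas$event_id %||% seq_len(nrow(ohcas)))
  colnames(a) <- as.character(candidates$site_id %||% seq_len(nrow(candidates)))
  a
}

#' Drop OHCAs already covered by existing AEDs
#'
#' @param ohcas tibble with `lat`, `lon`.
#' @param existing_aeds tibble with `lat`, `lon` (may have zero rows).
#' @param radius coverage radius in metres.
#' @return the uncovered subset of `ohcas`, with the number removed attached
#'   as the `n_removed` attribute.
#' @export
remove_covered <- function(ohcas, existing_aeds, radius = 100) {
  assert_that_(radius > 0, "radius must be > 0")
  if (is.null(existing_aeds) || nrow(existing_aeds) == 0) {
    out <- ohcas
    attr(out, "n_removed") <- 0L
    return(out)
  }
  d <- haversine_matrix(ohcas, existing_aeds)
  covered <- rowSums(d <= radius + 1e-6) > 0
  out <- ohcas[!covered, , drop = FALSE]
  attr(out, "n_removed") <- sum(covered)
  out
}

#' Construct a maximal-covering problem
#'
#' @param a binary OHCA x site coverage matrix (see
#'   [build_coverage_matrix()]).
#' @param N number of sites to select (0 <= N <= ncol(a)).
#' @param radius coverage radius the matrix was built with (metadata).
#' @return list of class `coverage_problem`.
#' @export
coverage_problem <- function(a, N, radius = NA_real_) {
  a <- as.matrix(a)
  assert_that_(all(a %in% c(0L, 1L)), "coverage matrix must be binary")
  assert_that_(N >= 0, "budget N must be >= 0")
  if (N > ncol(a)) {
    stop(sprintf("infeasible: budget N = %d exceeds %d candidate sites",
                 N, ncol(a)), call. = FALSE)
  }
  if (is.null(rownames(a))) rownames(a) <- as.character(seq_len(nrow(a)))
  if (is.null(colnames(a))) colnames(a) <- as.character(seq_len(ncol(a)))
  structure(list(a = a, N = as.integer(N), radius = radius),
            class = "coverage_problem")
}

#' Build a coverage problem from point tables
#'
#' Candidate sites at identical coordinates are collapsed to the one with the
#' lowest id before solving (duplicates only create degenerate alternate
#' optima).
#'
#' @param ohcas,candidates point tibbles (`lat`, `lon`, optional ids).
#' @param radius coverage radius in metres.
#' @param N budget.
#' @return a [coverage_problem()].
#' @export
make_coverage_problem <- function(ohcas, candidates, radius = 100, N = 100) {
  if (is.null(candidates$site_id)) candidates$site_id <- seq_len(nrow(candidates))
  candidates <- candidates[order(candidates$site_id), , drop = FALSE]
  dup <- duplicated(candidates[, c("lat", "lon")])
  coverage_problem(build_coverage_matrix(ohcas, candidates[!dup, , drop = FALSE],
                                         radius),
                   N = min(N, sum(!dup)), radius = radius)
}

#' @noRd
new_coverage_solution <- function(problem, sel_cols, objective, optimal,
                                  method) {
  a <- problem$a
  covered_rows <- if (length(sel_cols) > 0) {
    rowSums(a[, sel_cols, drop = FALSE]) > 0
  } else {
    rep(FALSE, nrow(a))
  }
  structure(list(
    selected = colnames(a)[sort(sel_cols)],
    covered = rownames(a)[covered_rows],
    objective = as.integer(objective),
    optimal = optimal,
    method = method,
    N = problem$N
  ), class = "coverage_solution")
}

#' Greedy maximal covering
#'
#' Iteratively adds the site covering the most currently uncovered OHCAs
#' (ties broken by lowest site position); classic submodular greedy with the
#' `1 - 1/e` approximation guarantee. Exactly `N` sites are returned (zero
#' marginal-gain sites fill any leftover budget, lowest ids first).
#'
#' @param problem a [coverage_problem()].
#' @return a `coverage_solution` (with `optimal = FALSE`: the objective is a
#'   lower bound unless verified against an exact solver).
#' @export
greedy_mclp <- function(problem) {
  stopifnot(inherits(problem, "coverage_problem"))
  a <- problem$a
  N <- problem$N
  uncovered <- rep(TRUE, nrow(a))
  available <- rep(TRUE, ncol(a))
  sel <- integer(0)
  for (k in seq_len(N)) {
    gains <- colSums(a[uncovered, , drop = FALSE])
    gains[!available] <- -1
    pick <- which.max(gains) # first max = lowest position
    sel <- c(sel, pick)
    available[pick] <- FALSE
    uncovered <- uncovered & !(a[, pick] > 0)
  }
  new_coverage_solution(problem, sel, sum(!uncovered),
                        optimal = (N == 0 || N == ncol(a)), method = "greedy")
}

#' Exact maximal covering by branch and bound
#'
#' Depth-first branch and bound over distinct coverage columns, pruned with
#' the submodular bound "current coverage plus the largest remaining marginal
#' gains" and seeded with the greedy incumbent. Once the optimal objective is
#' proven, a lexicographic reconstruction pass selects, among all
#' equal-objective optima, the set with the lowest site ids — a fully
#' deterministic tie-break.
#'
#' On very large instances the search budget can run out: the best incumbent
#' is then returned with `optimal = FALSE` (still deterministic; the greedy
#' lower bound and its `1 - 1/e` guarantee apply). If only the tie-break pass
#' runs out, the objective is still proven optimal.
#'
#' @param problem a [coverage_problem()].
#' @param node_limit maximum number of search nodes before falling back.
#' @param max_exact_cols instances with more distinct coverage columns than
#'   this skip the exact search and return the greedy solution directly
#'   (`optimal = FALSE`).
#' @return a `coverage_solution` with `optimal = TRUE` when solved to proven
#'   optimality.
#' @export
solve_mclp <- function(problem, node_limit = 5e5, max_exact_cols = 300) {
  stopifnot(inherits(problem, "coverage_problem"))
  a <- problem$a
  N <- problem$N
  n_row <- nrow(a)
  if (N == 0) {
    return(new_coverage_solution(problem, integer(0), 0L, TRUE, "branch_bound"))
  }
  env <- new.env()
  env$nodes <- 0L
  env$hit_limit <- FALSE

  # value-only bounded search: best coverage of `uncovered` using `budget`
  # columns chosen from `cols` (ascending), stopping early at `target`.
  # Depth-first via an explicit stack (instances can have thousands of
  # columns; native recursion would exhaust the C stack).
  max_cover <- function(uncovered, cols, budget, target, mat) {
    best <- 0L
    stack <- list(list(k = 1L, uncovered = uncovered, value = 0L,
                       budget = budget))
    while (length(stack) > 0 && !env$hit_limit) {
      node <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      env$nodes <- env$nodes + 1L
      if (env$nodes > node_limit) {
        env$hit_limit <- TRUE
        break
      }
      if (node$value > best) best <- node$value
      if (best >= target || node$budget == 0 || node$k > length(cols)) next
      rest <- cols[node$k:length(cols)]
      gains <- colSums(mat[node$uncovered, rest, drop = FALSE])
      ord <- sort(gains, decreasing = TRUE)
      bound <- node$value + sum(ord[seq_len(min(node$budget, length(ord)))])
      if (bound <= best) next
      cc <- cols[node$k]
      # push exclude first so the include branch is explored first
      stack[[length(stack) + 1L]] <- list(k = node$k + 1L,
                                          uncovered = node$uncovered,
                                          value = node$value,
                                          budget = node$budget)
      stack[[length(stack) + 1L]] <- list(
        k = node$k + 1L,
        uncovered = node$uncovered & mat[, cc] == 0,
        value = node$value + as.integer(sum(mat[node$uncovered, cc])),
        budget = node$budget - 1L)
    }
    best
  }

  # phase 1: optimal objective over distinct, useful columns
  pattern <- apply(a, 2, paste, collapse = "")
  cols <- which(!duplicated(pattern) & colSums(a) > 0)
  greedy <- greedy_mclp(problem)
  if (length(cols) > max_exact_cols && length(cols) > N) {
    # too many distinct columns for a worthwhile exact search
    return(new_coverage_solution(
      problem, match(greedy$selected, colnames(a)), greedy$objective,
      optimal = FALSE, method = "greedy (instance above exact-search size)"))
  }
  if (length(cols) <= N) {
    pad <- setdiff(seq_len(ncol(a)), cols)
    sel <- c(cols, pad[seq_len(N - length(cols))])
    obj <- sum(rowSums(a[, sel, drop = FALSE]) > 0)
    # everything useful is selected, but re-run the tie-break for lex order
    opt <- obj
  } else {
    opt <- max_cover(rep(TRUE, n_row), cols, N, n_row, a)
    opt <- max(opt, greedy$objective)
    if (env$hit_limit) {
      return(new_coverage_solution(
        problem, match(greedy$selected, colnames(a)), greedy$objective,
        optimal = FALSE, method = "branch_bound (node limit hit; greedy incumbent)"))
    }
  }

  # phase 2: lexicographically smallest optimal set over the original columns.
  # Duplicate columns share a coverage pattern; the completion search only
  # ever needs the lowest still-available id of each useful pattern, which
  # keeps each reachability check small even with thousands of candidates.
  useful <- which(colSums(a) > 0)
  groups <- split(useful, pattern[useful]) # each sorted ascending
  avail_after <- function(i) {
    ids <- vapply(groups, function(g) {
      g <- g[g > i]
      if (length(g)) g[1] else NA_integer_
    }, integer(1))
    sort(ids[!is.na(ids)])
  }
  uncovered <- rep(TRUE, n_row)
  chosen <- integer(0)
  budget <- N
  covered <- 0L
  i <- 1L
  n_col <- ncol(a)
  while (budget > 0 && !env$hit_limit) {
    if (n_col - i + 1L == budget) { # forced: take every remaining column
      chosen <- c(chosen, i:n_col)
      budget <- 0L
      break
    }
    gain <- sum(a[uncovered, i])
    rest <- avail_after(i)
    need <- opt - covered - gain
    reach <- if (need <= 0) 0L else max_cover(uncovered & a[, i] == 0,
                                              rest, budget - 1L, need, a)
    if (reach >= need) {
      chosen <- c(chosen, i)
      uncovered <- uncovered & a[, i] == 0
      covered <- covered + gain
      budget <- budget - 1L
    }
    i <- i + 1L
  }
  if (env$hit_limit || length(chosen) != N) {
    # tie-break pass ran out of nodes: fall back to the greedy set, but the
    # objective bound from phase 1 still certifies optimality when it matches
    sel <- match(greedy$selected, colnames(a))
    return(new_coverage_solution(problem, sel, greedy$objective,
                                 optimal = greedy$objective == opt,
                                 method = "branch_bound (greedy set; tie-break skipped)"))
  }
  obj <- sum(rowSums(a[, chosen, drop = FALSE]) > 0)
  new_coverage_solution(problem, chosen, obj, optimal = TRUE,
                        method = "branch_bound")
}

#' Exhaustive maximal covering (test oracle)
#'
#' Enumerates every size-`N` subset of candidate sites in lexicographic order
#' and keeps the first subset attaining the maximum coverage. Only intended
#' as an independent oracle on small instances.
#'
#' @param problem a [coverage_problem()].
#' @return a `coverage_solution` with `optimal = TRUE`.
#' @export
brute_force_mclp <- function(problem) {
  stopifnot(inherits(problem, "coverage_problem"))
  a <- problem$a
  N <- problem$N
  if (N == 0) {
    return(new_coverage_solution(problem, integer(0), 0L, TRUE, "brute_force"))
  }
  n_comb <- choose(ncol(a), N)
  if (n_comb > 1e6) {
    stop(sprintf("brute force would enumerate %.3g subsets (> 1e6)", n_comb),
         call. = FALSE)
  }
  combos <- utils::combn(ncol(a), N)
  objs <- apply(combos, 2, function(s) sum(rowSums(a[, s, drop = FALSE]) > 0))
  pick <- which.max(objs) # first max = lexicographically smallest subset
  new_coverage_solution(problem, combos[, pick], objs[pick], TRUE,
                        "brute_force")
}

#' @export
print.coverage_solution <- function(x, ...) {
  cat(sprintf("Maximal covering solution (%s): %d/%d sites, %d OHCAs covered%s\n",
              x$method, length(x$selected), x$N, x$objective,
              if (x$optimal) " (proven optimal)" else ""))
  invisible(x)
}
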