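#' Prior specification for the zero-inflated Poisson CAR model
#'
#' The zero-inflation probability is `p = exp(theta) / (1 + exp(theta))` with
#' a Gaussian prior on `theta`; the default `N(0.000001, variance 2)` implies
#' a prior mean of 0.5 for `p` with 2.5th/97.5th percentiles near 0.06/0.94.
#' Regression coefficients get independent `N(0, beta_prior_sd^2)` priors (on
#' the standardised covariate scale) and the ICAR and iid precisions get
#' Gamma(shape, rate) priors.
#'
#' @param theta_mean,theta_variance Gaussian prior on the logit of the
#'   zero-inflation probability.
#' @param beta_prior_sd prior standard deviation for intercept and
#'   coefficients.
#' @param tau_u_hyper,tau_v_hyper `c(shape, rate)` of the Gamma priors on the
#'   ICAR precision and on the precision of the unstructured effect.
#' @return a list of class `zip_car_prior`.
#' @export
zip_car_prior <- function(theta_mean = 1e-6, theta_variance = 2,
                          beta_prior_sd = 10,
                          tau_u_hyper = c(1, 5e-4),
                          tau_v_hyper = c(1, 5e-4)) {
  assert_that_(theta_variance > 0 && beta_prior_sd > 0 &&
                 all(tau_u_hyper > 0) && all(tau_v_hyper > 0),
               "prior variances and hyperparameters must be > 0")
  structure(list(theta_mean = theta_mean, theta_variance = theta_variance,
                 beta_prior_sd = beta_prior_sd,
                 tau_u_hyper = tau_u_hyper, tau_v_hyper = tau_v_hyper),
            class = "zip_car_prior")
}

#' Zero-inflated Poisson log-likelihood
#'
#' `sum(log(p * 1[y == 0] + (1 - p) * Poisson(y | lambda)))`: a point mass at
#' zero mixed with a Poisson, the "type 1" zero-inflation where the Poisson
#' component can itself produce zeros.
#'
#' @param y nonnegative integer counts.
#' @param lambda Poisson rates (> 0), recycled to `length(y)`.
#' @param p zero-inflation probability in `[0, 1]`.
#' @return the log-likelihood (scalar; `-Inf` for impossible data).
#' @examples
#' zip_log_likelihood(0, 1, 0.5) # log(0.5 + 0.5 * exp(-1))
#' @export
zip_log_likelihood <- function(y, lambda, p) {
  if (any(y < 0) || any(y != round(y))) {
    stop("y must contain nonnegative integers", call. = FALSE)
  }
  assert_that_(all(lambda > 0), "lambda must be > 0 elementwise")
  assert_that_(p >= 0 && p <= 1, "p must lie in [0, 1]")
  sum(log(p * (y == 0) + (1 - p) * stats::dpois(y, lambda)))
}

#' Prior-predictive summary of the zero-inflation probability
#'
#' Monte Carlo mean and central 95% interval of `plogis(theta)` under the
#' Gaussian prior on `theta`. With a symmetric prior centred (essentially) at
#' zero the mean is 0.5 by the symmetry of the logistic transform.
#'
#' @param prior a [zip_car_prior()].
#' @param n_draws Monte Carlo sample size (at least 1e5).
#' @param seed integer RNG seed.
#' @return list with `mean`, `q2.5`, `q97.5`, `n_draws` and the Monte Carlo
#'   standard error `se` of the mean.
#' @export
prior_p_summary <- function(prior = zip_car_prior(), n_draws = 1e6, seed = 1) {
  assert_that_(n_draws >= 1e5, "use at least 1e5 draws")
  p <- with_seed_(seed, {
    stats::plogis(stats::rnorm(n_draws, prior$theta_mean,
                               sqrt(prior$theta_variance)))
  })
  q <- stats::quantile(p, c(0.025, 0.975), names = FALSE)
  list(mean = mean(p), q2.5 = q[1], q97.5 = q[2],
       se = stats::sd(p) / sqrt(n_draws), n_draws = n_draws)
}

#' Poisson rate from the log-linear predictor
#'
#' `lambda = exp(beta0 + X beta + u + v)`.
#'
#' @param X covariate matrix (n x M); may have zero columns.
#' @param beta0 intercept.
#' @param beta coefficient vector of length M.
#' @param u,v random-effect vectors of length n (defaults 0).
#' @return strictly positive rate vector of length n.
#' @export
build_linear_predictor <- function(X, beta0, beta, u = 0, v = 0) {
  X <- as.matrix(X)
  assert_that_(ncol(X) == length(beta),
               sprintf("dimension mismatch: %d covariates vs %d coefficients",
                       ncol(X), length(beta)))
  eta <- beta0 + drop(X %*% beta) + u + v
  assert_that_(length(eta) == nrow(X), "u/v length must match nrow(X)")
  exp(eta)
}

#' Intrinsic CAR log-density (up to an additive constant)
#'
#' The pairwise-difference form `-(tau_u / 2) * sum over neighbour pairs
#' (u_i - u_j)^2`, equivalent to the conditional specification where each
#' `u_i` is normal about the mean of its neighbours with precision
#' `tau_u * n_i`.
#'
#' @param u effect vector (sum-to-zero by convention; the density itself is
#'   invariant to a constant shift).
#' @param adjacency neighbour list as from [build_adjacency()].
#' @param tau_u precision (> 0).
#' @return scalar log-density up to a constant.
#' @export
icar_log_density <- function(u, adjacency, tau_u) {
  assert_that_(tau_u > 0, "tau_u must be > 0")
  assert_that_(length(u) == length(adjacency), "u must match the adjacency")
  edges <- adjacency_edges(adjacency)
  -(tau_u / 2) * sum((u[edges[, 1]] - u[edges[, 2]])^2)
}

# ---- MCMC fitting ------------------------------------------------------------

#' Greedy graph colouring so same-colour cells are never neighbours
#' @noRd
colour_graph <- function(adj_pos) {
  n <- length(adj_pos)
  colour <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    used <- colour[adj_pos[[i]]]
    used <- used[!is.na(used)]
    colour[i] <- setdiff(seq_len(n), used)[1]
  }
  colour
}

#' Split-half R-hat for a single chain
#' @noRd
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  halves <- cbind(x[seq_len(n)], x[seq_len(n) + n])
  m <- colMeans(halves)
  w <- mean(apply(halves, 2, stats::var))
  b <- n * stats::var(m)
  if (w < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit the Bayesian zero-inflated Poisson model with BYM spatial effects
#'
#' Counts `y_i` on grid cells follow a zero-inflated Poisson: with probability
#' `p` a structural zero, otherwise Poisson with
#' `log(lambda_i) = beta0 + x_i' beta + u_i + v_i`, where `u` is an intrinsic
#' CAR (ICAR) field over the cell adjacency and `v` iid Gaussian noise.
#' Inference is by Markov chain Monte Carlo: structural zeros are imputed by
#' data augmentation; `theta` (the logit of `p`) and the regression block use
#' adaptive random-walk Metropolis; `u` is updated with chromatic (graph
#' coloured) vectorised single-site Metropolis steps and re-centred to sum to
#' zero at every iteration (the mean is absorbed into the intercept); the two
#' precisions have conjugate Gamma updates. Covariates are standardised
#' internally and all reported coefficients are back-transformed to the
#' original scale.
#'
#' @param cells grid tibble with a `y` count column and covariate columns.
#' @param adjacency neighbour list over exactly the rows of `cells` (see
#'   [build_adjacency()]); must be connected.
#' @param covariates character vector of covariate column names; by default
#'   every numeric column except the structural ones
#'   (`cell_id`, `row`, `col`, centroids, ids, `y`, ...).
#' @param prior a [zip_car_prior()].
#' @param n_iter,n_burn total and burn-in iterations.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed.
#' @param demand `"zip_mean"` (default): predicted count is the posterior
#'   mean of `(1 - p) * lambda_i`, the mean of the zero-inflated mixture;
#'   `"lambda_mean"`: posterior mean of `lambda_i` only.
#' @return object of class `zip_car_fit`: posterior draws (`beta0`, `beta`,
#'   `theta`, `p`, `tau_u`, `sigma_v`, `u`, `v`), a per-cell summary tibble
#'   (`cell_id`, `pred_mean`, `pred_sd`, `residual`), a coefficient table
#'   (posterior mean, 95% interval, `P(>0)`), split-R-hat diagnostics, a
#'   `converged` flag, and acceptance rates.
#' @export
fit_zip_car <- function(cells, adjacency, covariates = NULL,
                        prior = zip_car_prior(),
                        n_iter = 6000, n_burn = 2000, thin = 2, seed = 1,
                        demand = c("zip_mean", "lambda_mean")) {
  demand <- match.arg(demand)
  assert_that_(nrow(cells) >= 2, "need at least 2 cells")
  assert_that_("y" %in% names(cells), "cells must have a count column 'y'")
  assert_that_(length(adjacency) == nrow(cells),
               "adjacency must cover exactly the rows of cells")
  if (max(adjacency_components(adjacency)) > 1) {
    stop("adjacency graph is disconnected; fit components separately",
         call. = FALSE)
  }
  structural <- c("cell_id", "row", "col", "centroid_lat", "centroid_lon",
                  "municipality_id", "n_cells_municipality", "y",
                  "urban_rural")
  if (is.null(covariates)) {
    covariates <- names(cells)[vapply(cells, is.numeric, logical(1))]
    covariates <- setdiff(covariates, structural)
  }
  y <- as.integer(cells$y)
  assert_that_(all(y >= 0), "counts must be nonnegative")
  n <- length(y)
  M <- length(covariates)
  X <- as.matrix(cells[, covariates, drop = FALSE])
  if (M > 0) {
    x_mean <- colMeans(X)
    x_sd <- apply(X, 2, stats::sd)
    assert_that_(all(x_sd > 0),
                 sprintf("degenerate covariate(s): %s",
                         paste(covariates[x_sd == 0], collapse = ", ")))
    Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  } else {
    x_mean <- x_sd <- numeric(0)
    Xs <- matrix(0, n, 0)
  }

  # adjacency bookkeeping: positional indices, edges, CSR neighbour lists,
  # and a greedy graph colouring (same-colour cells are never adjacent, so
  # the ICAR field can be updated one colour class at a time)
  pos <- stats::setNames(seq_len(n), names(adjacency))
  adj_pos <- lapply(adjacency, function(nb) unname(pos[as.character(nb)]))
  edges <- adjacency_edges(adjacency)
  deg <- lengths(adj_pos)
  colour <- colour_graph(adj_pos)
  nbr_flat <- unlist(adj_pos)
  nbr_ptr <- c(0L, cumsum(deg))

  # Q x_m and quadratic forms used by the likelihood-invariant swap moves
  nbr_sum_of <- function(w) {
    s <- numeric(n)
    if (nrow(edges) > 0) {
      add1 <- rowsum(w[edges[, 2]], edges[, 1])
      s[as.integer(rownames(add1))] <- s[as.integer(rownames(add1))] + add1
      add2 <- rowsum(w[edges[, 1]], edges[, 2])
      s[as.integer(rownames(add2))] <- s[as.integer(rownames(add2))] + add2
    }
    s
  }
  Qx <- if (M > 0) {
    apply(Xs, 2, function(x) deg * x - nbr_sum_of(x))
  } else {
    matrix(0, n, 0)
  }
  xQx <- if (M > 0) colSums(Xs * Qx) else numeric(0)
  xnorm2 <- if (M > 0) colSums(Xs^2) else numeric(0)

  a_u <- prior$tau_u_hyper[1]; b_u <- prior$tau_u_hyper[2]
  a_v <- prior$tau_v_hyper[1]; b_v <- prior$tau_v_hyper[2]
  sd_b <- prior$beta_prior_sd

  n_keep <- floor((n_iter - n_burn) / thin)
  assert_that_(n_keep >= 10, "too few retained draws; increase n_iter")

  res <- with_seed_(seed, {
    b_init <- c(log(mean(y) + 0.1), rep(0, M))
    if (M > 0) {
      ml <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(1, Xs), y,
                                        family = stats::poisson())),
        error = function(e) NULL)
      if (!is.null(ml) && all(is.finite(ml$coefficients))) {
        b_init <- unname(ml$coefficients)
      }
    }
    .zip_car_mcmc(
      y = y, Xs = Xs, edges = edges - 1L,
      nbr = as.integer(nbr_flat) - 1L, nbr_ptr = as.integer(nbr_ptr),
      colour = as.integer(colour), Qx = Qx, xQx = xQx, xnorm2 = xnorm2,
      b_init = b_init,
      theta_mean = prior$theta_mean, theta_var = prior$theta_variance,
      sd_b = sd_b, a_u = a_u, b_u = b_u, a_v = a_v, b_v = b_v,
      n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
      thin = as.integer(thin), demand_zip = (demand == "zip_mean"))
  })
  res$acc_final <- res$acc
  # arma vectors come back as n x 1 matrices
  for (nm in c("theta", "tau_u", "tau_v", "pred_sum", "pred_sq", "lam_sum")) {
    res[[nm]] <- as.numeric(res[[nm]])
  }

  # back-transform coefficients to the raw covariate scale
  beta_std <- res$beta
  if (M > 0) {
    beta_raw <- sweep(beta_std[, -1, drop = FALSE], 2, x_sd, "/")
    beta0_raw <- beta_std[, 1] - drop(beta_raw %*% x_mean)
  } else {
    beta_raw <- beta_std[, 0, drop = FALSE]
    beta0_raw <- beta_std[, 1]
  }
  colnames(beta_raw) <- covariates
  p_draws <- stats::plogis(res$theta)

  pred_mean <- res$pred_sum / res$kept
  pred_sd <- sqrt(pmax(0, res$pred_sq / res$kept - pred_mean^2))
  summary_cells <- tibble::tibble(
    cell_id = cells$cell_id,
    y = y,
    pred_mean = pred_mean,
    pred_sd = pred_sd,
    lambda_mean = res$lam_sum / res$kept,
    residual = y - pred_mean
  )

  coef_draws <- cbind(`(Intercept)` = beta0_raw, beta_raw)
  coef_table <- tibble::tibble(
    term = colnames(coef_draws),
    mean = colMeans(coef_draws),
    q2.5 = apply(coef_draws, 2, stats::quantile, 0.025),
    q97.5 = apply(coef_draws, 2, stats::quantile, 0.975),
    prob_positive = colMeans(coef_draws > 0)
  )

  rhat <- c(
    beta0 = split_rhat(beta_std[, 1]),
    if (M > 0) stats::setNames(apply(beta_std[, -1, drop = FALSE], 2,
                                     split_rhat),
                               paste0("beta_", covariates)),
    theta = split_rhat(res$theta),
    log_tau_u = split_rhat(log(res$tau_u)),
    log_sigma_v = split_rhat(log(1 / sqrt(res$tau_v)))
  )
  converged <- all(is.finite(rhat)) && max(rhat) < 1.05
  if (!converged) {
    warning("fit_zip_car: split R-hat >= 1.05 for some parameters; ",
            "inspect $rhat and consider more iterations", call. = FALSE)
  }

  structure(list(
    draws = list(beta0 = beta0_raw, beta = beta_raw, theta = res$theta,
                 p = p_draws, tau_u = res$tau_u,
                 sigma_v = 1 / sqrt(res$tau_v), u = res$u, v = res$v),
    cells = summary_cells,
    coef_table = coef_table,
    rhat = rhat,
    converged = converged,
    accept = res$acc_final,
    covariates = covariates,
    demand = demand,
    prior = prior,
    n_iter = n_iter, n_burn = n_burn, thin = thin, seed = seed
  ), class = "zip_car_fit")
}

#' @export
print.zip_car_fit <- function(x, ...) {
  cat(sprintf(
    "Zero-inflated Poisson CAR fit: %d cells, %d covariates, %d draws\n",
    nrow(x$cells), length(x$covariates), length(x$draws$theta)))
  cat(sprintf("posterior mean p = %.3f; max split R-hat = %.3f (%s)\n",
              mean(x$draws$p), max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  print(x$coef_table)
  invisible(x)
}

# ---- Moran's I ---------------------------------------------------------------

#' Global Moran's I with a permutation test
#'
#' `I = (n / S0) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` with binary
#' contiguity weights and mean-centred values `z`. The p-value is the
#' one-sided permutation probability of observing autocorrelation at least as
#' positive as the data (random relabelling of the residuals over the cells).
#'
#' @param residuals numeric vector (e.g. observed minus posterior-mean count).
#' @param adjacency neighbour list as from [build_adjacency()].
#' @param n_permutations number of random relabellings.
#' @param seed integer RNG seed.
#' @return list with `I`, `p_value`, `n_permutations`.
#' @export
morans_i <- function(residuals, adjacency, n_permutations = 999, seed = 1) {
  n <- length(residuals)
  assert_that_(n == length(adjacency), "residuals must match the adjacency")
  z <- residuals - mean(residuals)
  if (sum(z^2) < .Machine$double.eps) {
    stop("Moran's I is undefined for constant residuals", call. = FALSE)
  }
  edges <- adjacency_edges(adjacency)
  s0 <- 2 * nrow(edges) # binary symmetric weights
  stat <- function(z) {
    (n / s0) * (2 * sum(z[edges[, 1]] * z[edges[, 2]])) / sum(z^2)
  }
  i_obs <- stat(z)
  i_perm <- with_seed_(seed, {
    vapply(seq_len(n_permutations),
           function(k) stat(z[sample.int(n)]), numeric(1))
  })
  p_value <- (1 + sum(i_perm >= i_obs)) / (n_permutations + 1)
  list(I = i_obs, p_value = p_value, n_permutations = n_permutations)
}
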