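test_that("ZIP log-likelihood matches closed forms and reduces to Poisson", {
  expect_equal(zip_log_likelihood(0, 1, 0.5), log(0.5 + 0.5 * exp(-1)))
  expect_equal(zip_log_likelihood(0, 1, 0.5), -0.3798855, tolerance = 1e-6)
  expect_equal(zip_log_likelihood(2, 2, 0), -2 + log(2), tolerance = 1e-12)
  expect_equal(zip_log_likelihood(1, 1, 1), -Inf)

  # p = 0 collapses to the Poisson log-likelihood for arbitrary inputs
  set.seed(5)
  for (k in 1:20) {
    y <- rpois(15, 3)
    lam <- rgamma(15, 2, 0.5)
    expect_equal(zip_log_likelihood(y, lam, 0),
                 sum(dpois(y, lam, log = TRUE)))
  }
  expect_error(zip_log_likelihood(-1, 1, 0.5), "nonnegative")
  expect_error(zip_log_likelihood(1.5, 1, 0.5), "integer")
})

test_that("prior on the zero-inflation probability is centred at one half", {
  s <- prior_p_summary(zip_car_prior(), n_draws = 2e5, seed = 1)
  expect_lt(abs(s$mean - 0.5), 3 * s$se)
  # percentile symmetry about 0.5 for a zero-centred theta prior
  s0 <- prior_p_summary(zip_car_prior(theta_mean = 0), n_draws = 2e5, seed = 2)
  expect_equal(s0$q2.5 + s0$q97.5, 1, tolerance = 0.01)
  # the stated prior implies a wide but not uniform p: (0.059, 0.941)
  expect_lt(abs(s$q2.5 - 0.059), 0.005)
  expect_lt(abs(s$q97.5 - 0.941), 0.005)
  # degenerate prior: point mass at one half
  sd0 <- prior_p_summary(zip_car_prior(theta_mean = 0, theta_variance = 1e-12),
                         n_draws = 1e5, seed = 3)
  expect_equal(sd0$mean, 0.5, tolerance = 1e-5)
})

test_that("log-linear predictor obeys the link's algebra", {
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(build_linear_predictor(matrix(0, 3, 0), 0, numeric(0)),
               rep(1, 3))
  expect_equal(build_linear_predictor(matrix(0, 3, 1), log(3), 0), rep(3, 3))
  lam <- build_linear_predictor(X, 0.5, c(1, -1))
  expect_equal(build_linear_predictor(X, 0.5 + 2, c(1, -1)), lam * exp(2))
  expect_true(all(lam > 0))
  expect_error(build_linear_predictor(X, 0, c(1, 2, 3)), "mismatch")
})

test_that("ICAR log-density follows the pairwise-difference form", {
  g2 <- toy_grid(1, 2)
  adj2 <- build_adjacency(g2, "rook")
  expect_equal(icar_log_density(c(0, 0), adj2, 3), 0)
  a <- 0.7
  expect_equal(icar_log_density(c(a, -a), adj2, 2), -(2 / 2) * (2 * a)^2)
  # linear in the precision
  expect_equal(icar_log_density(c(a, -a), adj2, 4),
               2 * icar_log_density(c(a, -a), adj2, 2))
  # invariant to a constant shift
  g <- toy_grid(3, 3)
  adj <- build_adjacency(g, "rook")
  u <- rnorm(9)
  expect_equal(icar_log_density(u, adj, 1.3),
               icar_log_density(u + 5, adj, 1.3))
})

test_that("Moran's I reproduces the checkerboard value and rejects constants", {
  g <- toy_grid(2, 2)
  adj <- build_adjacency(g, "rook")
  # cells row-major: (1,1), (1,2), (2,1), (2,2); checkerboard +1/-1
  mi <- morans_i(c(1, -1, -1, 1), adj, n_permutations = 99, seed = 1)
  expect_equal(mi$I, -1)
  expect_error(morans_i(rep(2, 4), adj), "constant")

  # positive autocorrelation on a split lattice is detected
  g6 <- toy_grid(6, 6)
  adj6 <- build_adjacency(g6, "rook")
  smooth <- ifelse(g6$col <= 3, 1, -1) + rnorm(36, 0, 0.1)
  mi2 <- morans_i(smooth, adj6, n_permutations = 499, seed = 2)
  expect_gt(mi2$I, 0.5)
  expect_lt(mi2$p_value, 0.05)
})

test_that("the fitted model recovers a signal-dominant synthetic dataset", {
  bundle <- simulate_study(synthetic_region_config(seed = 77),
                           generative_params(beta0 = 0.7, p_zero = 0.1))
  fit <- suppressWarnings(fit_zip_car(bundle$cells, bundle$adjacency,
                                      n_iter = 12000, n_burn = 5000, thin = 4,
                                      seed = 3))
  # posterior predictions track the observed counts (perfect-fit line check)
  expect_gt(cor(fit$cells$pred_mean, bundle$cells$y, method = "spearman"),
            0.5)
  # global residual balance when the intercept is identified
  expect_lt(abs(mean(fit$cells$residual)), 0.1 * mean(bundle$cells$y))
  expect_true(all(fit$cells$pred_mean >= 0))
  # zero-inflation probability near its generative value
  expect_lt(abs(mean(fit$draws$p) - 0.1), 0.15)
  # the ICAR field stays sum-to-zero in every stored draw
  expect_lt(max(abs(rowSums(fit$draws$u))), 1e-6)
  # structure of the returned object
  expect_named(fit$cells,
               c("cell_id", "y", "pred_mean", "pred_sd", "lambda_mean",
                 "residual"))
  expect_equal(nrow(fit$coef_table), 10)
})

test_that("fit validates its inputs", {
  g <- toy_grid(2, 2)
  g$y <- c(1L, 0L, 2L, 0L)
  adj <- build_adjacency(g)
  expect_error(fit_zip_car(g[1:2, ], adj), "adjacency")
  g$flat <- 1
  expect_error(suppressWarnings(fit_zip_car(g, adj, covariates = "flat",
                                            n_iter = 400, n_burn = 100)),
               "degenerate")
})
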