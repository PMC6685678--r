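test_that("region generation yields a contiguous, reproducible partition", {
  # single municipality swallows the whole lattice
  r1 <- generate_region(synthetic_region_config(2, 2, n_municipalities = 1))
  expect_equal(r1$cells$municipality_id, rep(1, 4))

  cfg <- synthetic_region_config(10, 10, n_municipalities = 4, seed = 1)
  r <- generate_region(cfg)
  expect_equal(sort(unique(r$cells$municipality_id)), 1:4)
  expect_false(anyNA(r$cells$municipality_id))
  expect_equal(sum(r$municipalities$n_cells), 100)

  # contiguity: each municipality's cells form one connected block
  for (m in 1:4) {
    sub <- r$cells[r$cells$municipality_id == m, ]
    attr(sub, "grid_spec") <- attr(r$cells, "grid_spec")
    adj <- build_adjacency(sub, "rook")
    comps <- aedaccess:::adjacency_components(adj)
    expect_equal(max(comps), 1)
  }

  # determinism
  r2 <- generate_region(cfg)
  expect_identical(r$cells$municipality_id, r2$cells$municipality_id)

  expect_error(synthetic_region_config(2, 2, n_municipalities = 5),
               "invalid config")
})

test_that("synthetic covariates respect their ranges and scale", {
  r <- generate_region(synthetic_region_config(12, 12, n_municipalities = 115,
                                               seed = 3))
  covs <- generate_covariates(r, seed = 5)
  expect_equal(nrow(covs), 115)
  expect_true(all(covs$prop_male > 0 & covs$prop_male < 1))
  expect_true(all(covs$prop_over_65 > 0 & covs$prop_over_65 < 1))
  ha <- as.matrix(covs[, startsWith(names(covs), "ha_")])
  expect_true(all(ha >= 0))
  # land uses cannot exceed the municipality area (121 ha per cell)
  r_area <- r$municipalities$n_cells * 121
  expect_true(all(rowSums(ha) <= r_area + 1e-9))
  expect_true(all(covs$urban_rural %in% c("urban", "rural")))
  expect_identical(covs, generate_covariates(r, seed = 5))
})

test_that("ICAR field draws satisfy the sum-to-zero constraint and shrink with tau", {
  g <- toy_grid(3, 3)
  adj <- build_adjacency(g, "rook")
  u <- simulate_icar_field(adj, tau_u = 1, seed = 2)
  expect_lt(abs(sum(u)), 1e-8)
  u_tight <- simulate_icar_field(adj, tau_u = 1e8, seed = 2)
  expect_lt(max(abs(u_tight)), 1e-3)

  # disconnected graphs are refused with a component count
  adj_disc <- list(`1` = integer(0), `2` = integer(0))
  expect_error(simulate_icar_field(adj_disc, 1), "disconnected.*2 components")
})

test_that("ICAR draw covariance matches the pseudo-inverse of the precision", {
  skip_if_not_installed("MASS")
  g <- toy_grid(3, 3)
  adj <- build_adjacency(g, "rook")
  tau <- 2
  draws <- simulate_icar_field(adj, tau, seed = 4, n_draws = 5000)
  emp <- cov(draws)
  # independent oracle: dense Moore-Penrose inverse of Q = tau (D - W)
  W <- matrix(0, 9, 9)
  for (i in seq_along(adj)) W[i, adj[[i]]] <- 1
  Q <- tau * (diag(rowSums(W)) - W)
  oracle <- MASS::ginv(Q)
  expect_equal(emp, oracle, tolerance = 0.12, ignore_attr = TRUE)
  expect_lt(max(abs(emp - oracle)), 4 * max(diag(oracle)) / sqrt(5000) * 3)
})

test_that("simulated counts follow the zero-inflated Poisson mixture", {
  # degenerate mixture: everything is a structural zero
  g <- toy_grid(4, 4)
  g$x <- runif(16)
  p1 <- generative_params(beta0 = 1, beta = c(x = 0), p_zero = 1,
                          n_aeds = 2, n_buildings = 2)
  expect_true(all(simulate_ohca_data(g, p1, seed = 1)$cells$y == 0))

  # Poisson mean oracle: p = 0, constant rate 2 over 10,000 cells
  g2 <- build_grid(c(lon_min = 0, lon_max = 1, lat_min = 0, lat_max = 1), 0.01)
  g2$x <- rep(0, nrow(g2))
  p2 <- generative_params(beta0 = log(2), beta = c(x = 0), tau_u = Inf,
                          sigma_v = 0, p_zero = 0, n_aeds = 2, n_buildings = 2)
  sim2 <- simulate_ohca_data(g2, p2, seed = 2)
  se <- sqrt(2 / nrow(g2))
  expect_lt(abs(mean(sim2$cells$y) - 2), 3 * se)

  # zero-fraction oracle: p + (1 - p) exp(-lambda) at p = 0.5, lambda = 5
  p3 <- generative_params(beta0 = log(5), beta = c(x = 0), tau_u = Inf,
                          sigma_v = 0, p_zero = 0.5, n_aeds = 2,
                          n_buildings = 2)
  sim3 <- simulate_ohca_data(g2, p3, seed = 3)
  p0 <- 0.5 + 0.5 * exp(-5)
  se0 <- sqrt(p0 * (1 - p0) / nrow(g2))
  expect_lt(abs(mean(sim3$cells$y == 0) - p0), 4 * se0)
})

test_that("simulated bundles are seed-deterministic with points in range", {
  cfg <- synthetic_region_config(6, 6, n_municipalities = 4, seed = 8)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1$cells$y, b2$cells$y)
  expect_identical(b1$events, b2$events)
  expect_identical(b1$aeds, b2$aeds)
  expect_identical(b1$buildings, b2$buildings)

  # events fall inside the cell that generated them
  ids <- locate_cells(b1$events, b1$cells)
  expect_identical(ids, rep(b1$cells$cell_id, b1$cells$y))
  # AEDs and buildings inside the region bbox
  expect_true(all(b1$aeds$lat >= 46.0 & b1$aeds$lat <= 46.06))
  expect_true(all(b1$buildings$lon >= 8.7 & b1$buildings$lon <= 8.76))
})

test_that("default generative settings emulate a sparse registry at desk scale", {
  zero_frac <- mean_y <- max_y <- numeric(3)
  for (s in 1:3) {
    b <- simulate_study(synthetic_region_config(seed = s))
    zero_frac[s] <- mean(b$cells$y == 0)
    mean_y[s] <- mean(b$cells$y)
    max_y[s] <- max(b$cells$y)
  }
  # high zero share, mean count below one event per cell, urban maxima in
  # the tens (not thousands)
  expect_true(all(zero_frac > 0.7 & zero_frac < 0.9))
  expect_true(all(mean_y > 0.2 & mean_y < 1))
  expect_true(all(max_y >= 5 & max_y < 200))
})
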