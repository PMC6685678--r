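test_that("exponential decay kernel matches its closed form and is monotone", {
  cfg <- decay_config(d0 = 100)
  expect_equal(decay_weight(0, cfg), 1)
  expect_equal(decay_weight(100, cfg), 0)
  expect_equal(decay_weight(50, cfg),
               (exp(-0.125) - exp(-0.5)) / (1 - exp(-0.5)),
               tolerance = 1e-12)
  expect_equal(decay_weight(50, cfg), 0.7013666, tolerance = 1e-6)
  expect_equal(decay_weight(150, cfg), 0)

  d <- seq(0, 100, length.out = 1000)
  w <- decay_weight(d, cfg)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w) < 0)) # strictly decreasing on [0, d0]
  # continuity at the truncation radius
  expect_lt(decay_weight(100 - 1e-6, cfg), 1e-6)
})

test_that("stepwise kernel is piecewise constant with nonincreasing weights", {
  cfg <- decay_config(d0 = 100, kind = "stepwise",
                      step_breaks = data.frame(radius = c(40, 100),
                                               weight = c(1, 0.5)))
  expect_equal(decay_weight(c(0, 40, 41, 100, 101), cfg),
               c(1, 1, 0.5, 0.5, 0))
  # default stepwise: indicator of the catchment
  flat <- decay_config(100, "stepwise")
  expect_equal(decay_weight(c(0, 99, 100, 100.1), flat), c(1, 1, 1, 0))
  expect_error(decay_config(100, "stepwise",
                            data.frame(radius = c(40, 100),
                                       weight = c(0.5, 1))),
               "nonincreasing")
})

test_that("supply-to-demand ratios follow the weighted-demand formula", {
  cfg <- decay_config(d0 = 100)
  aed <- tibble::tibble(aed_id = 1, lat = 0, lon = 0)
  # demand at distance zero, weight 1: R = S / D = 1/2
  r0 <- supply_demand_ratio(aed, tibble::tibble(cell_id = 1, lat = 0, lon = 0,
                                                demand = 2), cfg)
  expect_equal(r0$ratio, 0.5)
  expect_false(r0$zero_demand)

  # demand point 50 m north: R = 1 / (10 * G(50))
  lat50 <- 50 / 111194.9266
  r1 <- supply_demand_ratio(aed, tibble::tibble(cell_id = 1, lat = lat50,
                                                lon = 0, demand = 10), cfg)
  expect_equal(r1$ratio, 0.142580, tolerance = 1e-4)

  # nothing within the catchment: flagged, ratio zero
  r2 <- supply_demand_ratio(aed, tibble::tibble(cell_id = 1, lat = 1, lon = 1,
                                                demand = 10), cfg)
  expect_equal(r2$ratio, 0)
  expect_true(r2$zero_demand)

  # monotonicity: more demand in the catchment never raises the ratio
  base <- tibble::tibble(cell_id = 1:2, lat = c(0, lat50), lon = 0,
                         demand = c(1, 2))
  more <- base
  more$demand <- base$demand + c(0.5, 3)
  expect_lte(supply_demand_ratio(aed, more, cfg)$ratio,
             supply_demand_ratio(aed, base, cfg)$ratio)
})

test_that("access scores sum per-cell ratios and conserve their total", {
  g <- toy_grid(2, 2)
  aeds <- tibble::tibble(aed_id = 1:3,
                         lat = c(0.004, 0.006, 0.015),
                         lon = c(0.004, 0.006, 0.015))
  ratios <- tibble::tibble(aed_id = 1:3, ratio = c(0.3, 0.2, 0.4),
                           zero_demand = FALSE)
  sc <- access_scores(aeds, ratios, g)
  expect_equal(sc$access[sc$row == 1 & sc$col == 1], 0.5) # two AEDs share it
  expect_equal(sc$access[sc$row == 2 & sc$col == 2], 0.4)
  expect_equal(sc$access[sc$row == 1 & sc$col == 2], 0)
  expect_equal(sum(sc$access), sum(ratios$ratio))
})

test_that("end-to-end access conserves ratios on a synthetic study", {
  bundle <- simulate_study(synthetic_region_config(
    lattice_rows = 8, lattice_cols = 8, n_municipalities = 5, seed = 11),
    generative_params(n_aeds = 25, n_buildings = 50))
  cells <- bundle$cells
  cells$pred_mean <- pmax(bundle$truth$lambda, 0) # any nonneg demand works here
  acc <- compute_access(bundle$aeds, cells, "pred_mean", decay_config(100))
  expect_equal(sum(acc$cells$access), sum(acc$ratios$ratio),
               tolerance = 1e-10)
  expect_true(all(acc$ratios$ratio[acc$ratios$zero_demand] == 0))
  expect_true(all(acc$cells$access >= 0))
})

test_that("availability filter removes time-limited AEDs from supply", {
  cfg <- decay_config(d0 = 100)
  aeds <- tibble::tibble(aed_id = 1:2, lat = 0, lon = 0,
                         availability = c("public_24_7", "time_limited"))
  dem <- tibble::tibble(cell_id = 1, lat = 0, lon = 0, demand = 2)
  r <- supply_demand_ratio(aeds, dem, cfg, public_only = TRUE)
  expect_equal(r$ratio, c(0.5, 0))
})
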