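test_that("build_grid tiles the bounding box with half-open cells", {
  g <- build_grid(c(lon_min = 0, lon_max = 0.03, lat_min = 0, lat_max = 0.02),
                  0.01)
  expect_equal(nrow(g), 6) # 3 x 2
  expect_equal(max(g$col), 3)
  expect_equal(max(g$row), 2)

  # one-cell bbox
  g1 <- build_grid(c(lon_min = 0, lon_max = 0.01, lat_min = 0, lat_max = 0.01),
                   0.01)
  expect_equal(nrow(g1), 1)

  # every interior point maps to exactly one cell
  set.seed(1)
  pts <- data.frame(lon = runif(200, 0, 0.03), lat = runif(200, 0, 0.02))
  ids <- locate_cells(pts, g)
  expect_false(anyNA(ids))
  expect_true(all(ids %in% g$cell_id))

  # a shared-edge point belongs to the cell on its upper/right side
  edge <- data.frame(lon = 0.01, lat = 0.005)
  expect_equal(locate_cells(edge, g), g$cell_id[g$row == 1 & g$col == 2])

  expect_error(build_grid(c(lon_min = 1, lon_max = 0, lat_min = 0,
                            lat_max = 1), 0.01), "inverted")
})

test_that("assign_municipality uses centroid containment and flags overlaps", {
  g <- toy_grid(2, 2)
  # left column in municipality 1, right column in municipality 2
  region <- toy_region(data.frame(municipality_id = 1:2,
                                  lon0 = c(0, 0.01), lat0 = 0,
                                  lon1 = c(0.01, 0.02), lat1 = 0.02))
  a <- assign_municipality(g, region)
  expect_equal(a$municipality_id[a$col == 1], c(1, 1))
  expect_equal(a$municipality_id[a$col == 2], c(2, 2))

  # centroid outside all polygons -> NA
  region_small <- toy_region(data.frame(municipality_id = 1,
                                        lon0 = 0, lat0 = 0,
                                        lon1 = 0.01, lat1 = 0.02))
  a2 <- assign_municipality(g, region_small)
  expect_true(all(is.na(a2$municipality_id[a2$col == 2])))
  expect_equal(sum(!is.na(a2$municipality_id)), 2)

  # overlapping polygons claiming a centroid -> error naming offenders
  region_overlap <- toy_region(data.frame(municipality_id = 1:2,
                                          lon0 = 0, lat0 = 0,
                                          lon1 = 0.02, lat1 = 0.02))
  expect_error(assign_municipality(g, region_overlap), "overlapping.*1, 2")
})

test_that("covariate disaggregation conserves municipality totals", {
  g <- toy_grid(2, 5)
  g$municipality_id <- rep(1:2, each = 5)
  covs <- tibble::tibble(municipality_id = 1:2, a = c(10, 3), b = c(1, 7))
  d <- disaggregate_covariates(g, covs)
  # 10 / 5 cells = 2 each; single source of the worked division rule
  expect_equal(d$a[d$municipality_id == 1], rep(2, 5))
  # conservation for every municipality and covariate
  sums <- aggregate(cbind(a, b) ~ municipality_id, data = d, FUN = sum)
  expect_equal(sums$a, covs$a, tolerance = 1e-12)
  expect_equal(sums$b, covs$b, tolerance = 1e-12)

  # single-cell municipality keeps the full value
  g1 <- toy_grid(1, 1)
  g1$municipality_id <- 1
  d1 <- disaggregate_covariates(g1, covs[1, ])
  expect_equal(d1$a, 10)
})

test_that("count_events conserves events and resolves edges deterministically", {
  g <- toy_grid(2, 2)
  expect_equal(count_events(data.frame(lat = numeric(0), lon = numeric(0)),
                            g)$y, rep(0L, 4))

  ev <- data.frame(lat = rep(0.005, 5), lon = rep(0.005, 5))
  cnt <- count_events(ev, g)
  expect_equal(sum(cnt$y), 5)
  expect_equal(cnt$y[cnt$row == 1 & cnt$col == 1], 5)

  # event on a shared edge lands in exactly one cell (half-open rule)
  cnt2 <- count_events(data.frame(lat = 0.01, lon = 0.005), g)
  expect_equal(sum(cnt2$y), 1)
  expect_equal(cnt2$y[cnt2$row == 2 & cnt2$col == 1], 1)

  # out-of-grid events are reported, not dropped silently
  expect_message(
    cnt3 <- count_events(data.frame(lat = c(0.005, 5), lon = c(0.005, 5)), g),
    "1 event")
  expect_equal(sum(cnt3$y) + attr(cnt3, "n_outside"), 2)

  expect_error(count_events(data.frame(lat = 95, lon = 0), g), "out-of-range")
})

test_that("adjacency matches rook/queen contiguity and is symmetric", {
  g <- toy_grid(3, 3)
  rook <- build_adjacency(g, "rook")
  queen <- build_adjacency(g, "queen")
  centre <- g$cell_id[g$row == 2 & g$col == 2]
  corner <- g$cell_id[g$row == 1 & g$col == 1]
  expect_length(rook[[as.character(centre)]], 4)
  expect_length(rook[[as.character(corner)]], 2)
  expect_length(queen[[as.character(centre)]], 8)

  for (adj in list(rook, queen)) {
    for (i in names(adj)) {
      expect_false(as.integer(i) %in% adj[[i]])
      for (j in adj[[i]]) {
        expect_true(as.integer(i) %in% adj[[as.character(j)]])
      }
    }
  }
})
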