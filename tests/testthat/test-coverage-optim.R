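test_that("haversine distances match the spherical closed forms", {
  p00 <- data.frame(lat = 0, lon = 0)
  expect_equal(haversine_matrix(p00, p00)[1, 1], 0)
  # one degree of arc on the R = 6,371 km sphere
  expect_equal(haversine_matrix(p00, data.frame(lat = 1, lon = 0))[1, 1],
               pi * 6371000 / 180, tolerance = 1e-9)
  expect_equal(haversine_matrix(p00, data.frame(lat = 1, lon = 0))[1, 1],
               111194.9, tolerance = 1e-4)
  expect_error(haversine_matrix(data.frame(lat = 95, lon = 0), p00),
               "out-of-range")
})

test_that("haversine agrees with geosphere and satisfies metric properties", {
  set.seed(3)
  pts <- data.frame(lat = runif(6, -60, 60), lon = runif(6, -170, 170))
  ours <- haversine_matrix(pts, pts)
  ref <- geosphere::distm(cbind(pts$lon, pts$lat),
                          fun = function(a, b) {
                            geosphere::distHaversine(a, b, r = 6371000)
                          })
  expect_equal(ours, ref, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ours, t(ours))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(ours[i, j], ours[i, k] + ours[k, j] + 1e-9)
  }
})

test_that("coverage matrix uses a closed boundary at the radius", {
  m <- 1 / 111194.9266 # about one metre in degrees latitude
  ohcas <- data.frame(event_id = 1:3, lat = c(0, 100 * m, 150 * m), lon = 0)
  cand <- data.frame(site_id = 1, lat = 0, lon = 0)
  a <- build_coverage_matrix(ohcas, cand, radius = 100)
  expect_equal(as.vector(a), c(1L, 1L, 0L)) # colocated, exactly-at, beyond
  far <- build_coverage_matrix(data.frame(event_id = 1, lat = 1, lon = 1),
                               cand, 100)
  expect_equal(sum(far), 0)
})

test_that("remove_covered drops exactly the OHCAs near existing AEDs", {
  m <- 1 / 111194.9266
  ohcas <- data.frame(event_id = 1:3, lat = c(0, 0.005, 0.01), lon = 0)
  expect_equal(nrow(remove_covered(ohcas, ohcas[0, ], 100)), 3)
  aed <- data.frame(lat = 50 * m, lon = 0)
  kept <- remove_covered(ohcas, aed, 100)
  expect_equal(kept$event_id, c(2L, 3L))
  expect_equal(attr(kept, "n_removed"), 1L)
  all_cov <- remove_covered(ohcas, ohcas, 100)
  expect_equal(nrow(all_cov), 0)
})

test_that("exact solver handles the textbook cases with lexicographic ties", {
  a <- matrix(c(1, 1, 0,
                0, 0, 1), nrow = 3)
  sol <- solve_mclp(coverage_problem(a, 1))
  expect_equal(sol$selected, "1")
  expect_equal(sol$objective, 2L)
  expect_true(sol$optimal)

  expect_equal(solve_mclp(coverage_problem(a, 0))$objective, 0L)
  full <- solve_mclp(coverage_problem(a, 2))
  expect_equal(full$objective, 3L) # everything coverable is covered
  expect_error(coverage_problem(a, 3), "infeasible")

  # equal-objective optima resolved toward the lowest site ids
  tie <- matrix(c(1, 0,
                  0, 1), nrow = 2, byrow = TRUE)
  expect_equal(solve_mclp(coverage_problem(tie, 1))$selected, "1")
})

test_that("exact, greedy and brute force agree as required on random instances", {
  set.seed(42)
  for (k in 1:60) {
    I <- sample(3:10, 1)
    J <- sample(3:25, 1)
    N <- sample(1:min(4, I), 1)
    prob <- random_coverage_problem(J, I, N)
    exact <- solve_mclp(prob)
    brute <- brute_force_mclp(prob)
    greedy <- greedy_mclp(prob)
    expect_true(exact$optimal)
    expect_identical(exact$objective, brute$objective)
    expect_identical(exact$selected, brute$selected) # same lex tie-break
    expect_lte(greedy$objective, exact$objective)
    expect_gte(greedy$objective + 1e-9, (1 - exp(-1)) * exact$objective)
    expect_length(exact$selected, N)
  }
})

test_that("optimal objective is monotone in candidates and budget", {
  set.seed(7)
  for (k in 1:20) {
    prob <- random_coverage_problem(15, 8, 2)
    base <- solve_mclp(prob)$objective
    # an extra candidate site never hurts
    grown <- coverage_problem(cbind(prob$a,
                                    rbinom(15, 1, 0.3)), 2)
    expect_gte(solve_mclp(grown)$objective, base)
    # a bigger budget never hurts
    expect_gte(solve_mclp(coverage_problem(prob$a, 3))$objective, base)
  }
})

test_that("solver is deterministic and collapses duplicate candidate sites", {
  set.seed(9)
  prob <- random_coverage_problem(20, 9, 3)
  s1 <- solve_mclp(prob)
  s2 <- solve_mclp(prob)
  expect_identical(s1$selected, s2$selected)

  ohcas <- data.frame(event_id = 1:2, lat = c(0, 0.01), lon = 0)
  cands <- data.frame(site_id = 1:3, lat = c(0, 0, 0.01), lon = 0)
  prob2 <- make_coverage_problem(ohcas, cands, radius = 100, N = 2)
  expect_equal(ncol(prob2$a), 2) # sites 1 and 2 are colocated
  sol <- solve_mclp(prob2)
  expect_equal(sol$objective, 2L)
  expect_equal(sol$selected, c("1", "3"))
})
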