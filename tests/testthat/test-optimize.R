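test_that("scalarize maps observed extremes to 0 and 1", {
  rg <- response_ranges(study$responses)
  expect_equal(scalarize(rg["max", ], rep(1, 4), rg), 1)
  expect_equal(scalarize(rg["min", ], rep(1, 4), rg), 0)
  pred <- c(tpc = 50, tfc = 30, dpph = 20, abts = 30)
  expect_equal(scalarize(pred, c(1, 0, 0, 0), rg),
               as.numeric((50 - rg["min", "tpc"]) / diff(rg[, "tpc"])))
  expect_error(scalarize(pred, c(0, 0, 0, 0), rg), "not all zero")
})

test_that("scalarize is invariant to a common rescaling", {
  rg <- response_ranges(study$responses)
  P <- as.matrix(study$responses[1:5, ])
  expect_equal(scalarize(3 * P, c(1, 2, 1, 1), 3 * rg),
               scalarize(P, c(1, 2, 1, 1), rg))
})

test_that("GA finds the interior maximum of a planted concave quadratic", {
  ctr <- c(0.3, -0.4, 0.1, 0.6)
  fn <- function(P) {
    d <- sweep(P, 2, ctr)
    matrix(1 - rowSums(d^2), ncol = 1)
  }
  cfg <- ga_config(seed = 8, weights = 1,
                   bounds = matrix(rep(c(-1, 1), 4), 2))
  res <- ga_optimize(fn, cfg, ranges = rbind(min = 0, max = 1))
  # coordinates within 2% of the box range of the analytic arg-max
  expect_lt(max(abs(res$best - ctr)), 0.04)
  expect_equal(res$fitness, scalarize(fn(matrix(res$best, 1)), 1,
                                      rbind(min = 0, max = 1)))
})

test_that("GA runs are deterministic and never below seeded candidates", {
  fn <- rsm_predict_fn()
  rg <- response_ranges(study$responses)
  cfg <- ga_config(seed = 4, generations = 40)
  pts <- coded_matrix(study$design)
  a <- ga_optimize(fn, cfg, rg, factors = sh_factors(), init_points = pts)
  b <- ga_optimize(fn, cfg, rg, factors = sh_factors(), init_points = pts)
  expect_identical(a$best, b$best)
  expect_identical(a$trace, b$trace)
  expect_gte(a$fitness, max(scalarize(fn(pts), cfg$weights, rg)))
  # best-ever fitness is monotone across generations (elitism)
  expect_true(all(diff(a$trace) >= 0))
  expect_true(all(a$best >= -1 & a$best <= 1))
})

test_that("GA matches the exhaustive lattice oracle on the RSM surface", {
  fn <- rsm_predict_fn()
  rg <- response_ranges(study$responses)
  for (w in list(rep(1, 4), c(1, 0, 0, 0))) {
    cfg <- ga_config(seed = 2, weights = w)
    ga <- ga_optimize(fn, cfg, rg, factors = sh_factors(),
                      init_points = coded_matrix(study$design))
    oracle <- grid_search_oracle(fn, resolution = 21,
                                 bounds = matrix(rep(c(-1, 1), 4), 2),
                                 weights = w, ranges = rg)
    expect_gte(ga$fitness, oracle$fitness - 1e-3)
  }
})

test_that("lattice oracle at the design levels equals the best design point", {
  fn <- rsm_predict_fn()
  rg <- response_ranges(study$responses)
  w <- rep(1, 4)
  o3 <- grid_search_oracle(fn, resolution = 3,
                           bounds = matrix(rep(c(-1, 1), 4), 2),
                           weights = w, ranges = rg)
  # resolution-3 lattice = all +/-1/0 patterns, a superset of the design
  design_fit <- scalarize(fn(coded_matrix(study$design)), w, rg)
  expect_gte(o3$fitness, max(design_fit))
  expect_error(grid_search_oracle(fn, resolution = 2,
                                  bounds = matrix(rep(c(-1, 1), 4), 2),
                                  weights = w, ranges = rg), ">= 3")
  expect_error(grid_search_oracle(fn, resolution = 100,
                                  bounds = matrix(rep(c(-1, 1), 4), 2),
                                  weights = w, ranges = rg, cap = 1e4),
               "cap")
})

test_that("snapped factors are reported at a design level", {
  fn <- rsm_predict_fn()
  rg <- response_ranges(study$responses)
  cfg <- ga_config(seed = 1, generations = 20)
  res <- ga_optimize(fn, cfg, rg, factors = sh_factors(),
                     snap = "freq_kHz")
  expect_true(res$best_actual["freq_kHz"] %in% c(26, 35, 40))
})

test_that("ga_config validates its invariants", {
  expect_error(ga_config(pop = 3), ">= 4")
  expect_error(ga_config(weights = c(-1, 1, 1, 1)), "non-negative")
  expect_error(ga_config(bounds = matrix(c(1, -1), 2)), "lo < hi")
  expect_error(ga_config(elitism = 50, pop = 50), "elitism")
})
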