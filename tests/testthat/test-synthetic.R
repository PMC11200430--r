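test_that("the packaged study has the published shape and extrema", {
  expect_equal(nrow(study$design), 27)
  expect_equal(names(study$responses), c("tpc", "tfc", "dpph", "abts"))
  expect_equal(max(study$responses$tpc), 71.80)
  expect_equal(which.max(study$responses$tpc), 4L)
  expect_equal(min(study$responses$tfc), 20.08)
  expect_equal(which.min(study$responses$tfc), 2L)
  expect_equal(range(study$responses$tpc), c(44.28, 71.80))
  expect_equal(range(study$responses$dpph), c(13.06, 31.41))
  expect_equal(range(study$responses$abts), c(20.03, 49.29))
  expect_equal(which(study$design$is_center), c(11L, 20L, 27L))
  expect_length(validate_design(study$design, lack_of_fit = TRUE), 0)
  expect_false(anyNA(study$sd))
})

test_that("generate_study is reproducible and honors the seed", {
  truth <- sh_truth(seed = 21)
  a <- generate_study(sh_factors(), truth)
  b <- generate_study(sh_factors(), truth)
  expect_identical(a$responses, b$responses)
  c <- generate_study(sh_factors(), sh_truth(seed = 22))
  expect_false(identical(a$responses, c$responses))
  expect_equal(dim(a$responses), c(27, 4))
})

test_that("zero-noise simulation returns the exact surface", {
  truth <- sh_truth(noise_sd = 0, seed = 1)
  sim <- generate_study(sh_factors(), truth)
  for (r in colnames(truth$beta)) {
    m <- fit_quadratic(sim$design, sim$responses[[r]])
    expect_equal(unname(coef(m)), unname(truth$beta[, r]),
                 tolerance = 1e-8)
  }
})

test_that("ground_truth validates dimensions against the factors", {
  beta <- quad_beta(sh_factors(), `(Intercept)` = 1)
  expect_error(generate_study(sh_factors()[1:3],
                              ground_truth(beta, 1)), "do not match")
  expect_error(ground_truth(unname(beta), 1), "term names")
  expect_error(ground_truth(beta, -1), ">= 0")
})

test_that("noise at a 10:1 signal variance ratio lands r2 in (0.8, 1)", {
  truth0 <- sh_truth(noise_sd = 0, seed = 1)
  signal <- generate_study(sh_factors(), truth0)$responses$tpc
  sd10 <- sqrt(var(signal) / 10)
  ok <- 0L
  for (s in 1:200) {
    sim <- generate_study(sh_factors(),
                          ground_truth(truth0$beta[, "tpc", drop = FALSE],
                                       sd10, seed = s))
    r2 <- adequacy(fit_quadratic(sim$design, sim$responses[[1]]))$r2
    ok <- ok + (r2 > 0.8 && r2 < 1)
  }
  expect_gte(ok / 200, 0.90)
})

test_that("mean fitted coefficients recover the truth across replicates", {
  truth <- sh_truth(seed = 1)
  beta <- truth$beta[, "tpc"]
  est <- matrix(NA_real_, 200, length(beta))
  for (s in 1:200) {
    sim <- generate_study(sh_factors(),
                          ground_truth(truth$beta[, "tpc", drop = FALSE],
                                       truth$noise_sd["tpc"], seed = s))
    est[s, ] <- coef(fit_quadratic(sim$design, sim$responses[[1]]))
  }
  se_mean <- apply(est, 2, sd) / sqrt(200)
  within <- abs(colMeans(est) - beta) <= 2 * se_mean
  expect_gte(mean(within), 0.95)
})
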