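test_that("noise-free quadratic responses are recovered exactly", {
  f <- sh_factors()
  beta <- quad_beta(f, `(Intercept)` = 60, ethanol_pct = -4, time_min = 2,
                    `I(ethanol_pct^2)` = -6, `I(freq_kHz^2)` = -3,
                    `ethanol_pct:temp_C` = 1.5)
  sim <- generate_study(f, ground_truth(beta, noise_sd = 0, seed = 1))
  m <- fit_quadratic(sim$design, sim$responses[[1]])
  expect_equal(unname(coef(m)), unname(beta), tolerance = 1e-8)
  a <- adequacy(m)
  expect_equal(a$r2, 1, tolerance = 1e-10)
  expect_equal(a$cv_percent, 0, tolerance = 1e-6)
  expect_identical(a$adequate_precision, Inf)
})

test_that("prediction at the coded origin equals the intercept", {
  # ordinal coding: the physical center point is the coded origin
  m_ord <- fit_quadratic(study$design, study$responses$tpc,
                         scheme = "ordinal")
  center <- data.frame(ethanol_pct = 50, time_min = 35, temp_C = 40,
                       freq_kHz = 35)
  expect_equal(predict(m_ord, center), unname(coef(m_ord)[1]))
  # affine coding: the coded origin of the unequally spaced frequency
  # factor sits at 33 kHz, not at the 35 kHz center level
  origin <- as.data.frame(lapply(sh_factors(), decode_value, coded = 0,
                                 scheme = "affine"))
  names(origin) <- names(center)
  for (m in study_fits)
    expect_equal(predict(m, origin), unname(coef(m)[1]))
})

test_that("the fit reproduces the study's published predicted values", {
  for (r in names(study_fits)) {
    expect_lt(max(abs(predict(study_fits[[r]]) - study$rsm_pred[[r]])),
              0.05)
    # all three center replicates get one identical prediction
    expect_length(unique(round(predict(study_fits[[r]])[c(11, 20, 27)], 8)),
                  1)
  }
})

test_that("fit_quadratic validates its inputs", {
  expect_error(fit_quadratic(study$design, study$responses$tpc[-1]),
               "does not match")
  y <- study$responses$tpc; y[3] <- NA
  expect_error(fit_quadratic(study$design, y), "missing")
  few <- as_bbd_design(as.data.frame(study$design)[1:12, ], sh_factors())
  expect_error(fit_quadratic(few, study$responses$tpc[1:12]), "at least")
})

test_that("ANOVA satisfies the sum-of-squares identities", {
  for (m in study_fits) {
    a <- as.data.frame(anova(m))
    g <- function(s) a[a$source == s, ]
    expect_equal(g("Model")$ss + g("Residual")$ss, g("Total")$ss)
    expect_equal(g("Lack of fit")$ss + g("Pure error")$ss, g("Residual")$ss)
    expect_equal(g("Lack of fit")$df + g("Pure error")$df, g("Residual")$df)
    expect_equal(g("Model")$df + g("Residual")$df, g("Total")$df)
    expect_equal(g("Residual")$df, 12)
  }
})

test_that("lack-of-fit partition is omitted without replicates", {
  f <- sh_factors()
  sim <- generate_study(f, sh_truth(seed = 3), n_center = 1)
  m <- fit_quadratic(sim$design, sim$responses$tpc)
  expect_warning(a <- anova(m), "no replicated")
  expect_false("Lack of fit" %in% a$source)
})

test_that("model space is closed under affine recoding of the factors", {
  # the same polynomial fitted on raw actual units spans the same space,
  # so fitted values agree with the coded fit
  nm <- names(study$design)[2:5]
  dat <- cbind(study$design[nm], .y = study$responses$tpc)
  form <- as.formula(paste(".y ~", paste(nm, collapse = "+"), "+",
    paste(sprintf("I(%s^2)", nm), collapse = "+"), "+",
    paste(combn(nm, 2, paste, collapse = ":"), collapse = "+")))
  raw <- lm(form, dat)
  expect_equal(unname(fitted(raw)), predict(study_fits$tpc),
               tolerance = 1e-8)
})

test_that("the full model never fits worse than a sub-model", {
  coded <- as.data.frame(coded_matrix(study$design))
  for (r in names(study_fits)) {
    sub <- lm(study$responses[[r]] ~ ., data = coded)
    expect_gte(adequacy(study_fits[[r]])$r2, summary(sub)$r.squared)
  }
})

test_that("coefficient confidence intervals show nominal coverage", {
  f <- sh_factors()
  truth <- sh_truth()
  beta <- truth$beta[, "tpc"]
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    sim <- generate_study(f, ground_truth(beta, truth$noise_sd["tpc"],
                                          seed = s))
    m <- fit_quadratic(sim$design, sim$responses[[1]])
    ci <- confint(m$fit, level = 0.95)
    hits <- hits + sum(ci[, 1] <= beta & beta <= ci[, 2])
    total <- total + length(beta)
  }
  expect_gte(hits / total, 0.91)
  expect_lte(hits / total, 0.99)
})

test_that("surface_grid is consistent with direct prediction", {
  m <- study_fits$tpc
  g <- surface_grid(m, c("time_min", "temp_C"), resolution = 5)
  expect_equal(dim(g$pred), c(5, 5))
  expect_true(all(is.finite(g$pred)))
  corners <- expand.grid(a = c(1, 5), b = c(1, 5))
  for (i in seq_len(nrow(corners))) {
    pt <- data.frame(time_min = g$axis1[corners$a[i]],
                     temp_C = g$axis2[corners$b[i]],
                     ethanol_pct = 50, freq_kHz = 35)
    expect_equal(g$pred[corners$a[i], corners$b[i]], predict(m, pt))
  }
  expect_error(surface_grid(m, c("time_min", "time_min")), "distinct")
  expect_error(surface_grid(m, c("time_min", "temp_C"),
                            fixed = list(temp_C = 40)), "both varied and fixed")
})

test_that("grid arg-max matches a two-factor brute-force search", {
  m <- study_fits$tpc
  g <- surface_grid(m, c("time_min", "temp_C"), resolution = 41)
  idx <- arrayInd(which.max(g$pred), dim(g$pred))
  # independent oracle: exhaustive lattice over the same two coded axes
  f <- sh_factors()
  fn <- function(P) {
    pts <- data.frame(time_min = decode_value(f[[2]], P[, 1], "affine"),
                      temp_C = decode_value(f[[3]], P[, 2], "affine"),
                      ethanol_pct = 50, freq_kHz = 35)
    matrix(predict(m, pts), ncol = 1)
  }
  o <- grid_search_oracle(fn, resolution = 41,
                          bounds = matrix(rep(c(-1, 1), 2), 2),
                          weights = 1, ranges = rbind(min = 0, max = 100))
  expect_equal(unname(c(g$coded1[idx[1]], g$coded2[idx[2]])),
               unname(o$best))
})
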