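test_that("split sizes follow largest-remainder apportionment", {
  sp <- split_data(27, c(0.65, 0.20, 0.15), seed = 42)
  expect_equal(lengths(sp[c("train", "test", "val")]),
               c(train = 18, test = 5, val = 4))
  expect_equal(sort(c(sp$train, sp$test, sp$val)), 1:27)
  expect_equal(split_data(20, c(0.5, 0.25, 0.25), 1)$sizes, c(10, 5, 5))
  expect_identical(split_data(27, seed = 7), split_data(27, seed = 7))
  expect_error(split_data(4), ">= 5")
  expect_error(split_data(27, c(0.7, 0.3, 0)), "positive")
})

test_that("parameter count matches the topology", {
  ann <- train_ann(study$design, study$responses, n_hidden = 10, seed = 1,
                   max_iter = 2)
  expect_length(ann$par, 94)  # (4*10 + 10) + (10*4 + 4)
  expect_equal(dim(ann$weights$W1), c(10, 4))
  expect_equal(dim(ann$weights$W2), c(4, 10))
  casc <- train_ann(study$design, study$responses, n_hidden = 3, seed = 1,
                    max_iter = 2, cascade = TRUE)
  expect_length(casc$par, (4 * 3 + 3) + (3 * 4 + 4) + 4 * 4)
})

test_that("training is deterministic given data, seed and options", {
  a <- train_ann(study$design, study$responses, n_hidden = 6, seed = 5)
  b <- train_ann(study$design, study$responses, n_hidden = 6, seed = 5)
  expect_identical(a$par, b$par)
  expect_identical(predict_ann(a, study$design),
                   predict_ann(b, study$design))
})

test_that("a linear map is learned to near machine precision", {
  X <- coded_matrix(build_bbd(sh_factors(), 3), "affine")
  B <- matrix(c(1, -2, 0.5, 0, 0.3, 1, -1, 2, -0.5, 0.2, 0.1, -0.3,
                2, 0, 1, -1), 4, 4)
  Y <- X %*% B + matrix(rep(c(5, -3, 10, 0), each = nrow(X)), ncol = 4)
  for (alg in c("lm", "bfgs")) {
    ann <- train_ann(X, Y, n_hidden = 10, algorithm = alg, seed = 2,
                     max_iter = 1000)
    expect_lt(ann$train_mse, 1e-4)
    tr <- ann$split$train
    expect_lt(max(abs(predict_ann(ann, X[tr, ]) - Y[tr, ])), 1e-2)
  }
})

test_that("training MSE never ends above its starting value", {
  ann <- train_ann(study$design, study$responses, n_hidden = 8, seed = 9)
  h <- ann$mse_history$train_mse
  expect_lte(h[length(h)], h[1])
  expect_true(all(diff(h) <= 1e-12))
})

test_that("response scaling round-trips", {
  Y <- as.matrix(study$responses)
  sc <- uaeopt:::scale_minmax(Y)
  expect_equal(uaeopt:::unscale_minmax(sc$scaled, sc$lo, sc$hi), Y)
  expect_equal(range(sc$scaled[, 1]), c(-1, 1))
})

test_that("hidden-neuron sweep selects the validation minimizer", {
  sw <- sweep_hidden_neurons(study$design, study$responses, h_range = 1:6,
                             seed = 3)
  score <- ifelse(is.na(sw$table$val_mse), sw$table$train_mse,
                  sw$table$val_mse)
  expect_equal(sw$table$n_hidden[which.min(score)], sw$selected)
  expect_equal(sw$model$n_hidden, sw$selected)
  expect_equal(sweep_hidden_neurons(study$design, study$responses,
                                    h_range = 5, seed = 1)$selected, 5)
})

test_that("on noiseless quadratic data the sweep beats a single neuron", {
  sim <- generate_study(sh_factors(), sh_truth(noise_sd = 0, seed = 2))
  sw <- sweep_hidden_neurons(sim$design, sim$responses, h_range = c(1, 4, 8),
                             seed = 4)
  tab <- sw$table
  expect_lte(tab$val_mse[tab$n_hidden == sw$selected],
             tab$val_mse[tab$n_hidden == 1])
})

test_that("surrogates serialize to JSON and reload bit-exactly", {
  ann <- train_ann(study$design, study$responses, n_hidden = 4, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  ann_save(ann, path)
  back <- ann_load(path)
  expect_identical(back$par, ann$par)
  expect_identical(back$y_lo, ann$y_lo)
  expect_identical(predict_ann(back, study$design),
                   predict_ann(ann, study$design))
})

test_that("restarts keep the best validation score", {
  one <- train_ann(study$design, study$responses, n_hidden = 3, seed = 1)
  multi <- train_ann(study$design, study$responses, n_hidden = 3, seed = 1,
                     n_restarts = 4)
  expect_lte(multi$val_mse, one$val_mse)
})

test_that("invalid inputs are rejected", {
  expect_error(train_ann(study$design, study$responses, n_hidden = 0),
               "between 1 and 20")
  expect_error(train_ann(study$design, study$responses, n_hidden = 21),
               "between 1 and 20")
  y <- study$responses; y$tpc[1] <- Inf
  expect_error(train_ann(study$design, y, n_hidden = 3), "finite")
})
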