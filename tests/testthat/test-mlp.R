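test_that("the forward pass matches hand-computed networks", {
  # all-zero weights: constant prediction, the inverse transform of 0
  m0 <- new_mlp_model(matrix(0, 2, 4), c(0, 0), c(0, 0), 0)
  X <- matrix(runif(20, 0, 100), 5, 4)
  expect_equal(mlp_forward(m0, X), rep(0, 5))

  # single neuron, hand-set weights: w1 = 1, b1 = 0, w2 = 2, b2 = 0.5,
  # input 0 -> tanh(0) = 0 -> output 0.5
  m1 <- new_mlp_model(matrix(c(1, 0, 0, 0), 1, 4), 0, 2, 0.5)
  expect_equal(mlp_forward(m1, matrix(0, 1, 4)), 0.5)
  # and a non-trivial point: 2 * tanh(0.3) + 0.5
  expect_equal(mlp_forward(m1, matrix(c(0.3, 0, 0, 0), 1, 4)),
               2 * tanh(0.3) + 0.5)

  # saturation: |x| = 1000 drives tanh within 1e-9 of +/-1
  msat <- new_mlp_model(matrix(c(1, 0, 0, 0), 1, 4), 0, 1, 0)
  expect_equal(mlp_forward(msat, matrix(c(1000, 0, 0, 0), 1, 4)), 1,
               tolerance = 1e-9)
  expect_equal(mlp_forward(msat, matrix(c(-1000, 0, 0, 0), 1, 4)), -1,
               tolerance = 1e-9)
})

test_that("the forward pass validates input shape and weight finiteness", {
  m <- new_mlp_model(matrix(0, 2, 4), c(0, 0), c(0, 0), 0)
  expect_error(mlp_forward(m, matrix(0, 3, 3)), "input columns")
  expect_error(mlp_forward(m, data.frame(bs_pct = 1)), "missing input")
  expect_error(new_mlp_model(matrix(Inf, 1, 4), 0, 1, 0), "finite")
})

test_that("R2 and RMSE match their definitions", {
  obs <- c(1, 2, 3); pred <- c(1, 2, 5)
  expect_equal(rmse(obs, pred), sqrt(4 / 3))
  expect_equal(r_squared(obs, pred), -1)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(rmse(obs, obs), 0)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(rmse(1:3, 1:4), "equal length")
  expect_error(rmse(1, 1), "at least 2")
})

test_that("training represents a noiseless linear map almost exactly", {
  b <- generate_linear_benchmark(c(2, 1, 0.5, 0.25), intercept = 5,
                                 noise_sd = 0, n_records = 200, seed = 7)
  m <- train_mlp(as.matrix(b[, substrate_components()]), b$y, 3,
                 train_config(seed = 2))
  expect_gte(r_squared(b$y, mlp_forward(m, b[, substrate_components()])),
             0.999)
})

test_that("a constant target is fitted exactly by the bias-only network", {
  set.seed(1)
  X <- matrix(runif(40, 0, 100), 20, 2)
  colnames(X) <- c("a", "b")
  m <- suppressWarnings(train_mlp(X, rep(3.5, 20), 2,
                                  train_config(seed = 1)))
  expect_lte(rmse(rep(3.5, 20), mlp_forward(m, X)), 1e-6)
})

test_that("three hidden neurons represent two-input parity", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  colnames(X) <- c("x1", "x2")
  y <- c(0, 1, 1, 0)
  expect_warning(
    m <- train_mlp(X, y, 3, train_config(seed = 3, max_epochs = 5000,
                                         n_restarts = 5, patience = 500)),
    "overparameterized")
  expect_true(all(abs(mlp_forward(m, X) - y) < 0.1))
})

test_that("training is deterministic in its seed and beats the initial model", {
  b <- smooth_benchmark(80, seed = 6)
  X <- as.matrix(b[, substrate_components()])
  m1 <- train_mlp(X, b$resp, 4, train_config(seed = 10))
  m2 <- train_mlp(X, b$resp, 4, train_config(seed = 10))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$w2, m2$w2)
  m3 <- train_mlp(X, b$resp, 4, train_config(seed = 11))
  expect_false(identical(m1$W1, m3$W1))
  expect_lte(m1$fit$train_rmse_scaled, m1$fit$init_rmse_scaled)
})

test_that("model bundles survive a JSON round trip", {
  b <- smooth_benchmark(60, seed = 3)
  m <- train_mlp(as.matrix(b[, substrate_components()]), b$resp + 100, 3,
                 quick_cfg(4), lambda = 0.5)
  path <- tempfile(fileext = ".json")
  write_mlp_json(m, path)
  m2 <- read_mlp_json(path)
  X <- as.matrix(b[, substrate_components()])
  expect_equal(mlp_forward(m2, X), mlp_forward(m, X), tolerance = 1e-12)
  unlink(path)
})

test_that("best-achievable training error is non-increasing in capacity", {
  b <- smooth_benchmark(150, seed = 5)
  X <- as.matrix(b[, substrate_components()])
  best <- vapply(c(1, 2, 4, 8), function(h) {
    min(vapply(1:5, function(s) {
      m <- train_mlp(X, b$resp, h, train_config(seed = 100 + s))
      rmse(b$resp, mlp_forward(m, X))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(best) <= 1e-8))
})

test_that("cross-validation trains one model per replicate-fold and pools honestly", {
  d <- generate_replicates(tiny_summary(),
                           generator_config(n_replicates = 20, seed = 2))
  plan <- make_cv_plan(nrow(d), seed = 3, n_replicates = 2)
  rep_ <- crossval_evaluate(d, "YIELD", 2, plan, quick_cfg(5),
                            keep_models = TRUE)
  expect_equal(nrow(rep_$per_fold), 2 * 5)
  expect_length(rep_$models, 2 * 5)

  te <- rep_$predictions[rep_$predictions$subset == "test", ]
  for (r in 1:2) {
    idx <- sort(te$index[te$replicate == r])
    expect_equal(idx, seq_len(nrow(d))) # each record held out exactly once
  }
  # held-out records are excluded from their fold's training partition
  for (f in 1:5) {
    model <- rep_$models[[paste(1, f, sep = ".")]]
    held <- plan$folds[[1]][[f]]
    tr <- setdiff(seq_len(nrow(d)), held)
    expect_equal(unname(model$scalers$min),
                 unname(apply(as.matrix(d[tr, substrate_components()]),
                              2, min)))
  }
  # pooled metrics recompute exactly from the stored predictions
  pooled_test <- rep_$pooled[rep_$pooled$subset == "test", ]
  expect_equal(pooled_test$r2, r_squared(te$observed, te$predicted))
  expect_equal(pooled_test$rmse, rmse(te$observed, te$predicted))
})

test_that("scalers never see held-out records (leakage audit)", {
  d <- generate_replicates(tiny_summary(),
                           generator_config(n_replicates = 15, seed = 4))
  # make one record an extreme input... impossible: inputs are the design;
  # instead verify the target scaler ignores a held-out extreme response.
  plan <- make_cv_plan(nrow(d), seed = 6, n_replicates = 1)
  f <- 2
  held <- plan$folds[[1]][[f]]
  d2 <- as.data.frame(d)
  d2$yield_g[held[1]] <- 10 * max(d2$yield_g)
  rep_ <- crossval_evaluate(d2, "yield_g", 2, plan, quick_cfg(7),
                            boxcox = "none", keep_models = TRUE)
  model <- rep_$models[[paste(1, f, sep = ".")]]
  tr <- setdiff(seq_len(nrow(d2)), held)
  expect_equal(model$scalers$center, mean(d2$yield_g[tr]))
  expect_lt(model$scalers$center + model$scalers$halfrange,
            max(d2$yield_g))
})

test_that("cross-validated metrics detect signal and refuse to invent it", {
  b <- smooth_benchmark(150, seed = 5)
  plan <- make_cv_plan(150, seed = 9, n_replicates = 2)
  r <- crossval_evaluate(b, "resp", 5, plan, train_config(seed = 4),
                         boxcox = "none")
  expect_gte(r$pooled$r2[r$pooled$subset == "test"], 0.99)

  # negative control: permuted labels carry no signal
  set.seed(13)
  b$shuffled <- b$resp[sample(nrow(b))]
  r0 <- crossval_evaluate(b, "shuffled", 5, restrict_plan(plan, 1),
                          train_config(seed = 4), boxcox = "none")
  expect_lte(r0$pooled$r2[r0$pooled$subset == "test"], 0.2)
})

test_that("cross-validation reports are deterministic", {
  d <- generate_replicates(tiny_summary(),
                           generator_config(n_replicates = 12, seed = 5))
  plan <- make_cv_plan(nrow(d), seed = 2, n_replicates = 1)
  r1 <- crossval_evaluate(d, "BE", 3, plan, quick_cfg(8))
  r2 <- crossval_evaluate(d, "BE", 3, plan, quick_cfg(8))
  expect_identical(r1$pooled, r2$pooled)
  expect_identical(r1$predictions, r2$predictions)
})
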