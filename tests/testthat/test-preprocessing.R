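test_that("Box-Cox transform matches its closed forms and is continuous at 0", {
  expect_equal(boxcox_transform(c(1, 2, 4), 0), c(0, log(2), log(4)))
  expect_equal(boxcox_transform(c(1, 2, 4), 1), c(0, 1, 3))
  expect_equal(boxcox_transform(3, 2), 4)
  expect_equal(boxcox_transform(c(1, 2, 4), 1e-9),
               boxcox_transform(c(1, 2, 4), 0), tolerance = 1e-6)
  expect_error(boxcox_transform(c(1, -1), 1), "positive")
  # inverse round trip
  x <- c(0.5, 1, 7, 30)
  for (l in c(-1, -0.3, 0, 0.5, 2)) {
    expect_equal(boxcox_inverse(boxcox_transform(x, l), l), x,
                 tolerance = 1e-10)
  }
})

test_that("Box-Cox MLE equals an independently coded grid oracle", {
  # oracle: literal loop over the same grid with the textbook profile
  # log-likelihood, written without reusing the package's internals
  oracle <- function(x) {
    grid <- seq(-5, 5, by = 0.01)
    n <- length(x)
    ll <- numeric(length(grid))
    for (g in seq_along(grid)) {
      l <- grid[g]
      z <- if (l == 0) log(x) else (x^l - 1) / l
      ll[g] <- -n / 2 * log(sum((z - mean(z))^2) / n) +
        (l - 1) * sum(log(x))
    }
    grid[which.max(ll)]
  }
  set.seed(21)
  vectors <- list(exp(rnorm(500)),               # lognormal: lambda ~ 0
                  rnorm(500, 50, 5),             # shifted normal: ~ 1
                  rexp(300, 0.2) + 0.5,
                  runif(200, 1, 9)^3)
  for (x in vectors) {
    expect_equal(boxcox_mle(x)$lambda, oracle(x))
  }
  expect_lt(abs(boxcox_mle(vectors[[1]])$lambda), 0.15)
  expect_lt(abs(boxcox_mle(vectors[[2]])$lambda - 1), 0.3)
})

test_that("Box-Cox MLE agrees with the MASS profile at grid resolution", {
  set.seed(8)
  x <- rexp(400, 0.1) + 1
  ours <- boxcox_mle(x)$lambda
  mb <- MASS::boxcox(x ~ 1, lambda = seq(-5, 5, by = 0.01), plotit = FALSE)
  expect_equal(ours, mb$x[which.max(mb$y)], tolerance = 0.011)
})

test_that("Box-Cox MLE rejects degenerate input", {
  expect_error(boxcox_mle(rep(2, 10)), "constant")
  expect_error(boxcox_mle(c(1, 2)), "at least 3")
  expect_error(boxcox_mle(c(1, 2, -3)), "positive")
})

test_that("PCA screen flags a constructed gross outlier and nothing structureless", {
  d <- generate_replicates(substrate_trial_summary(),
                           generator_config(n_replicates = 12, seed = 42))
  resp_cols <- c("srp_days", "dphf_days", "dffh_days", "yield_g",
                 "be_pct", "tcp_days")
  X <- as.matrix(d[, resp_cols])
  # displace one record by 10 pooled SDs on every response
  X2 <- X
  X2[37, ] <- X2[37, ] + 10 * apply(X, 2, sd)
  scr <- pca_outlier_screen(X2)
  expect_true(scr$flag[37])

  # pure jitter: no structure to violate
  set.seed(3)
  J <- matrix(5 + rnorm(60 * 4, 0, 1e-4), 60, 4)
  expect_equal(sum(pca_outlier_screen(J)$flag), 0)

  expect_error(pca_outlier_screen(X[1:2, ]), "at least 3")
})

test_that("PCA screen returns audit scores for every record", {
  d <- smooth_benchmark(60, seed = 2)
  scr <- pca_outlier_screen(d)
  expect_length(scr$distance, 60)
  expect_length(scr$flag, 60)
  expect_true(scr$n_components >= 1)
})

test_that("scalers map training extrema to [-1, 1] and invert exactly", {
  set.seed(4)
  X <- matrix(runif(60, -3, 7), 20, 3)
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(20, 10, 2)
  sc <- fit_scalers(X, y)
  Xs <- scale_inputs(sc, X)
  expect_equal(unname(apply(Xs, 2, min)), rep(-1, 3))
  expect_equal(unname(apply(Xs, 2, max)), rep(1, 3))
  expect_equal(unscale_inputs(sc, Xs), X, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unscale_target(sc, scale_target(sc, y)), y,
               tolerance = 1e-12)
  # out-of-range values pass through unclipped
  out <- scale_inputs(sc, matrix(c(100, 100, 100), 1, 3))
  expect_true(all(out > 1))
  expect_error(fit_scalers(cbind(X, konst = rep(2, 20))), "konst")
})

test_that("cross-validation plans partition records with balanced folds", {
  plan <- make_cv_plan(192, seed = 1)
  expect_equal(plan$n_replicates, 10)
  for (r in seq_len(10)) {
    sizes <- sort(vapply(plan$folds[[r]], length, integer(1)),
                  decreasing = TRUE)
    expect_equal(sizes, c(39, 39, 38, 38, 38))
    all_idx <- sort(unlist(plan$folds[[r]]))
    expect_equal(all_idx, 1:192) # union = everything, pairwise disjoint
  }
  # replicates use distinct permutations
  expect_false(identical(plan$folds[[1]], plan$folds[[2]]))
})

test_that("plans are deterministic in (n, seed) and differ across seeds", {
  p1 <- make_cv_plan(50, seed = 1)
  p2 <- make_cv_plan(50, seed = 1)
  p3 <- make_cv_plan(50, seed = 2)
  expect_identical(p1$folds, p2$folds)
  expect_false(identical(p1$folds, p3$folds))
  expect_identical(cv_plan_hash(p1), cv_plan_hash(p2))
  expect_false(identical(cv_plan_hash(p1), cv_plan_hash(p3)))
  expect_error(make_cv_plan(3, seed = 1), "at least")
})

test_that("plans serialize to JSON with the replicate/fold structure", {
  plan <- make_cv_plan(20, seed = 5, k = 4, n_replicates = 2)
  parsed <- jsonlite::fromJSON(cv_plan_json(plan), simplifyVector = FALSE)
  expect_equal(parsed$n_records, 20)
  expect_length(parsed$folds, 2)
  expect_length(parsed$folds[[1]], 4)
})
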