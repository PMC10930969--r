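test_that("the RBF kernel matches its closed form", {
  x <- c(0.3, -1.2, 4)
  expect_equal(rbf_kernel(x, x, gamma = 7), 1)
  expect_equal(rbf_kernel(c(1, 2), c(5, -3), gamma = 0), 1)
  expect_equal(rbf_kernel(c(1, 1), c(0, 0), gamma = 0.5), exp(-1))
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), gamma = 1), "mismatch")
})

test_that("a singleton grid is returned as-is with its direct CV error", {
  X <- seeded_matrix(30, 5, seed = 50)
  y <- X[, 2] + seeded_vector(30, seed = 51, sd = 0.3)
  cfg <- rf_grid_config(ntree_grid = 80, mtry_grid = 3, k_folds = 3, seed = 2)
  fit <- grids_rf_fit(X, y, cfg)
  expect_identical(fit$best_hyperparameters, list(ntree = 80L, mtry = 3L))
  expect_identical(nrow(fit$cv_table), 1L)
  expect_identical(fit$cv_error, fit$cv_table$cv_mse[1])
})

test_that("grid-search winner matches independent re-evaluation of every grid point", {
  X <- seeded_matrix(40, 6, seed = 52)
  y <- X[, 1] + 0.5 * X[, 3] + seeded_vector(40, seed = 53, sd = 0.2)
  cfg <- rf_grid_config(
    ntree_grid = c(50, 100, 150), mtry_grid = c(2, 3, 4),
    k_folds = 4, seed = 9
  )
  fit <- grids_rf_fit(X, y, cfg)

  # oracle: re-fit every (ntree, mtry, fold) with the same derived seeds
  oracle <- vapply(seq_len(nrow(fit$cv_table)), function(i) {
    nt <- as.integer(fit$cv_table$ntree[i])
    mt <- as.integer(fit$cv_table$mtry[i])
    sq <- numeric(40)
    for (f in 1:4) {
      hold <- fit$folds == f
      rf <- epinir:::with_seed(
        derive_seed(9, sprintf("rf/%d/%d/%d", nt, mt, f)),
        randomForest::randomForest(
          x = X[!hold, , drop = FALSE], y = y[!hold],
          ntree = nt, mtry = mt
        )
      )
      sq[hold] <- (y[hold] - predict(rf, X[hold, , drop = FALSE]))^2
    }
    mean(sq)
  }, numeric(1))
  expect_equal(oracle, fit$cv_table$cv_mse, tolerance = 1e-12)
  best <- which.min(oracle)
  expect_identical(
    fit$best_hyperparameters,
    list(ntree = fit$cv_table$ntree[best], mtry = fit$cv_table$mtry[best])
  )
})

test_that("every sample sits in exactly one fold shared across the grid", {
  X <- seeded_matrix(23, 4, seed = 54)
  y <- seeded_vector(23, seed = 55)
  fit <- grids_rf_fit(X, y, rf_grid_config(ntree_grid = c(30, 60), k_folds = 5, seed = 3))
  expect_length(fit$folds, 23)
  expect_setequal(unique(fit$folds), 1:5)

  # determinism: same data + config + seed reproduces the winner
  fit2 <- grids_rf_fit(X, y, rf_grid_config(ntree_grid = c(30, 60), k_folds = 5, seed = 3))
  expect_identical(fit2$best_hyperparameters, fit$best_hyperparameters)
  expect_identical(fit2$cv_table, fit$cv_table)
})

test_that("constant responses tie-break to the smallest grid pair", {
  X <- seeded_matrix(20, 4, seed = 56)
  y <- rep(5, 20)
  fit <- suppressWarnings(grids_rf_fit(X, y, rf_grid_config(
    ntree_grid = c(50, 100),
    mtry_grid = c(2, 3), k_folds = 4, seed = 1
  )))
  expect_identical(fit$best_hyperparameters, list(ntree = 50L, mtry = 2L))
  expect_lt(fit$cv_error, 1e-20)
  expect_error(
    grids_rf_fit(X, y, rf_grid_config(mtry_grid = 10, seed = 1)),
    "exceed n_features"
  )
})

test_that("one-generation GA equals exhaustive evaluation of its population", {
  X <- seeded_matrix(30, 3, seed = 60)
  y <- X[, 1]^2 + seeded_vector(30, seed = 61, sd = 0.1)
  cfg <- ga_config(population_size = 4, n_generations = 1, k_folds = 3, seed = 8)
  fit <- ga_svr_fit(X, y, cfg)
  expect_identical(nrow(fit$initial_population), 4L)
  expect_length(fit$history, 1L)

  # oracle: evaluate the same four (c, gamma) pairs independently via e1071
  mses <- apply(fit$initial_population, 1, function(g) {
    sq <- numeric(30)
    for (f in unique(fit$folds)) {
      hold <- fit$folds == f
      m <- e1071::svm(
        x = X[!hold, , drop = FALSE], y = y[!hold],
        type = "eps-regression", kernel = "radial",
        cost = 10^g[1], gamma = 10^g[2], epsilon = cfg$epsilon, scale = FALSE
      )
      sq[hold] <- (y[hold] - predict(m, X[hold, , drop = FALSE]))^2
    }
    mean(sq)
  })
  expect_equal(fit$cv_error, min(mses), tolerance = 1e-12)
  expect_equal(fit$best_hyperparameters$cost,
    10^fit$initial_population[which.min(mses), 1],
    tolerance = 1e-12
  )
  expect_equal(fit$best_hyperparameters$gamma,
    10^fit$initial_population[which.min(mses), 2],
    tolerance = 1e-12
  )
})

test_that("GA best fitness never worsens between generations", {
  X <- seeded_matrix(40, 2, seed = 62)
  y <- sin(X[, 1]) + 0.3 * X[, 2] + seeded_vector(40, seed = 63, sd = 0.05)
  fit <- ga_svr_fit(X, y, ga_config(population_size = 10, n_generations = 12, seed = 4))
  expect_true(all(diff(fit$history) <= 1e-12))
  # seeded determinism
  fit2 <- ga_svr_fit(X, y, ga_config(population_size = 10, n_generations = 12, seed = 4))
  expect_identical(fit2$best_hyperparameters, fit$best_hyperparameters)
  expect_error(ga_svr_fit(X, rep(1, 40), ga_config(seed = 1)), "degenerate")
})

test_that("predictions are deterministic, shape-checked and row-consistent", {
  X <- seeded_matrix(30, 4, seed = 64)
  y <- X[, 1] + seeded_vector(30, seed = 65, sd = 0.1)
  fit <- ga_svr_fit(X, y, ga_config(population_size = 6, n_generations = 3, seed = 2))

  Xn <- seeded_matrix(8, 4, seed = 66)
  p1 <- predict(fit, Xn)
  expect_length(p1, 8)
  expect_identical(predict(fit, Xn), p1)
  # permutation of rows permutes predictions correspondingly
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  expect_equal(predict(fit, Xn[perm, ]), p1[perm], tolerance = 1e-12)
  # single-row input
  expect_length(predict(fit, Xn[1, , drop = FALSE]), 1)
  expect_error(predict(fit, Xn[, 1:3]), "expects 4")

  # a near-interpolating SVR reproduces its noiseless training surface
  y0 <- drop(X %*% c(1, -2, 0.5, 3))
  exact <- ga_svr_fit(X, y0, ga_config(
    population_size = 8, n_generations = 10,
    c_range = c(1, 1e3), seed = 5
  ))
  expect_lt(mean((y0 - predict(exact, X))^2), 1e-2)
})
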