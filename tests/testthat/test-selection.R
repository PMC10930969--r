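test_that("CARS weights normalise absolute coefficients to unit sum", {
  expect_equal(cars_weights(c(1, -1, 2)), c(0.25, 0.25, 0.5))
  for (s in 1:10) {
    b <- seeded_vector(20, seed = 700 + s)
    expect_equal(sum(cars_weights(b)), 1)
  }
  expect_error(cars_weights(c(0, 0)), "degenerate")
})

test_that("stability is the mean/sd ratio of coefficient trajectories", {
  expect_equal(uve_stability(matrix(c(1, 2, 3), 3, 1))[1], 2)
  expect_warning(h <- uve_stability(matrix(1, 3, 2)), "Inf")
  expect_true(all(h == Inf))
})

test_that("a single retain-all CARS run reduces to top-weight thresholding", {
  X <- seeded_matrix(30, 12, seed = 20)
  y <- X[, 3] + 0.5 * X[, 9] + seeded_vector(30, seed = 21, sd = 0.1)
  m <- 5L
  sel <- cars_select(X, y,
    n_mc_runs = 1, schedule = m, ars = FALSE, subsample = 1,
    n_components = 3, seed = 1
  )
  b <- pls_fit(X, y, 3)$coefficients
  expect_setequal(sel$selected, order(abs(b), decreasing = TRUE)[1:m])
})

test_that("CARS recovers planted variables across seeded runs", {
  hits <- sapply(1:20, function(s) {
    X <- seeded_matrix(60, 50, seed = 5000 + s)
    y <- X[, 10] + 0.8 * X[, 40] + seeded_vector(60, seed = 6000 + s, sd = 0.1)
    all(c(10, 40) %in% cars_select(X, y, seed = s)$selected)
  })
  expect_gte(sum(hits), 18)
})

test_that("SPA behaves like orthogonal projection on orthogonal designs", {
  # mutually orthogonal zero-mean columns of norms 3 > 2 > 1: projections
  # preserve norms, so from the norm-3 start the norm-2 column is added next
  X <- unclass(stats::poly(1:12, 3)) %*% diag(c(3, 2, 1))
  chain <- epinir:::spa_chain_for_test(X, start = 1, k = 3)
  expect_identical(chain, c(1L, 2L, 3L))
})

test_that("SPA chains match a brute-force Gram-Schmidt oracle", {
  gs_chain <- function(X, start, k) {
    Xc <- sweep(X, 2, colMeans(X))
    chain <- start
    for (step in 2:k) {
      basis <- qr.Q(qr(Xc[, chain, drop = FALSE]))
      resid <- Xc - basis %*% (t(basis) %*% Xc)
      norms <- sqrt(colSums(resid^2))
      norms[chain] <- -Inf
      chain <- c(chain, which.max(norms))
    }
    as.integer(chain)
  }
  for (s in 1:100) {
    X <- seeded_matrix(8, 6, seed = 800 + s)
    start <- 1 + (s %% 6)
    expect_identical(
      epinir:::spa_chain_for_test(X, start = start, k = 3),
      gs_chain(X, start, 3)
    )
  }
})

test_that("SPA-selected columns are mutually orthogonal after projection", {
  cal <- small_calibration(seed = 11)
  sel <- spa_select(cal$X, cal$y, k_max = 8)
  Xc <- sweep(cal$X, 2, colMeans(cal$X))
  chain <- sel$diagnostics$chain
  for (i in 2:length(chain)) {
    basis <- qr.Q(qr(Xc[, chain[1:(i - 1)], drop = FALSE]))
    r <- Xc[, chain[i]] - basis %*% (t(basis) %*% Xc[, chain[i]])
    # the residual must still be substantial, never annihilated
    expect_gt(sqrt(sum(r^2)), 1e-10)
  }
  # collinear column: projection annihilates it, so it is never selected
  X2 <- cbind(cal$X[, 1:20], cal$X[, 1] * 2)
  sel2 <- suppressWarnings(spa_select(X2, cal$y, k_max = 10))
  expect_false(all(c(1, 21) %in% sel2$selected))
})

test_that("UVE keeps only variables whose stability beats every noise variable", {
  X <- seeded_matrix(40, 30, seed = 40)
  y <- X[, 5] + seeded_vector(40, seed = 41, sd = 0.05)
  sel <- suppressWarnings(uve_select(X, y, seed = 1))
  h <- sel$diagnostics$stability
  thr <- sel$diagnostics$threshold
  expect_true(all(abs(h[sel$selected]) > thr))
  expect_equal(thr, max(abs(h[31:60])))
  unkept <- setdiff(1:30, sel$selected)
  expect_true(all(abs(h[unkept]) <= thr))
})

test_that("UVE recovers a planted predictor across seeded runs", {
  hits <- sapply(1:20, function(s) {
    X <- seeded_matrix(40, 30, seed = 3000 + s)
    y <- X[, 5] + seeded_vector(40, seed = 4000 + s, sd = 0.05)
    5 %in% suppressWarnings(uve_select(X, y, seed = s))$selected
  })
  expect_gte(sum(hits), 19)
})

test_that("selection results serialise to JSON and back", {
  cal <- small_calibration(seed = 11)
  sel <- spa_select(cal$X, cal$y, k_max = 6, wavenumbers = cal$wavenumbers)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  sel2 <- read_selection(path)
  expect_identical(sel2$selected, sel$selected)
  expect_identical(sel2$method, sel$method)
})
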