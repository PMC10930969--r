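# Independent brute-force max-min joint-distance partitioner: plain loops,
# no shared code with the implementation.
brute_spxy <- function(X, y, frac) {
  n <- nrow(X)
  dx <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  dy <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) dy[i, j] <- abs(y[i] - y[j])
  }
  d <- dx / max(dx) + dy / max(dy)
  n_cal <- floor(n * frac)
  best <- c(NA, NA)
  bestd <- -Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > bestd) {
        bestd <- d[i, j]
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(1:n, sel)
    score <- sapply(cand, function(i) min(d[i, sel]))
    sel <- c(sel, cand[which.max(score)])
  }
  sort(sel)
}

test_that("the farthest joint-distance pair seeds the calibration set", {
  y <- c(0, 10, 5, 5.1)
  X <- cbind(y, y) # spectra proportional to the response
  sp <- spxy_split(X, y, 0.5)
  expect_setequal(sp$calibration_ids, c("1", "2"))
})

test_that("splits agree with a brute-force max-min oracle on random instances", {
  for (s in 1:25) {
    n <- 6 + (s %% 7)
    X <- seeded_matrix(n, 4, seed = 300 + s)
    y <- seeded_vector(n, seed = 400 + s)
    frac <- c(0.5, 0.66, 0.75)[1 + (s %% 3)]
    sp <- spxy_split(X, y, frac)
    expect_identical(
      as.integer(sp$calibration_ids),
      brute_spxy(X, y, frac)
    )
  }
})

test_that("response extremes land in calibration when spectra track the response", {
  # when X is proportional to y the joint distance is monotone in |dy|, so
  # the two response extremes form the seeding pair; brute force confirms.
  # (For general X the spectral block can dominate and an extreme may stay
  # out — the guarantee is conditional, not universal.)
  for (s in 1:15) {
    n <- 8 + (s %% 5)
    y <- seeded_vector(n, seed = 600 + s)
    X <- cbind(2 * y, -y, 0.5 * y)
    sp <- spxy_split(X, y, 0.5)
    cal <- as.integer(sp$calibration_ids)
    expect_true(which.min(y) %in% cal)
    expect_true(which.max(y) %in% cal)
    expect_identical(sort(cal), brute_spxy(X, y, 0.5))
  }
  # unconditionally, the maximum joint-distance pair seeds the set
  for (s in 1:10) {
    X <- seeded_matrix(10, 3, seed = 500 + s)
    y <- seeded_vector(10, seed = 650 + s)
    d <- as.matrix(dist(X)) / max(dist(X)) + abs(outer(y, y, `-`)) / max(abs(outer(y, y, `-`)))
    pair <- which(d == max(d), arr.ind = TRUE)[1, ]
    cal <- as.integer(spxy_split(X, y, 0.5)$calibration_ids)
    expect_true(all(pair %in% cal))
  }
})

test_that("splitting is deterministic, disjoint and ratio-faithful", {
  d <- generate_spectra(small_config(), curves = FALSE)
  y <- d$hardness$F1
  s1 <- spxy_split(d$spectra, y, 0.75)
  s2 <- spxy_split(d$spectra, y, 0.75)
  expect_identical(s1, s2)
  expect_length(intersect(s1$calibration_ids, s1$prediction_ids), 0)
  expect_setequal(c(s1$calibration_ids, s1$prediction_ids), d$spectra$sample_ids)
  expect_identical(length(s1$calibration_ids), 36L) # floor(48 * 0.75)
})

test_that("degenerate blocks are rejected", {
  X <- matrix(1, 6, 3)
  expect_error(spxy_split(X, 1:6, 0.5), "all spectra identical")
  X2 <- seeded_matrix(6, 3, seed = 1)
  expect_error(spxy_split(X2, rep(2, 6), 0.5), "all responses identical")
  expect_error(spxy_split(X2[1:3, ], 1:3, 0.5), "at least 4")
})

test_that("baseline splitters partition with the requested ratio", {
  X <- seeded_matrix(20, 5, seed = 9)
  ks <- kennard_stone_split(X, 0.75)
  expect_length(ks$calibration_ids, 15L)
  rs <- random_split(X, 0.75, seed = 4)
  expect_length(rs$calibration_ids, 15L)
  expect_identical(random_split(X, 0.75, seed = 4), rs)
})

test_that("split JSON round trip preserves the partition", {
  X <- seeded_matrix(12, 4, seed = 2)
  y <- seeded_vector(12, seed = 3)
  sp <- spxy_split(X, y, 0.75)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(sp, path)
  expect_identical(read_split(path), sp)
})
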