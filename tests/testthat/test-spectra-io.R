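test_that("spectra CSV round trip preserves doubles exactly", {
  s <- spectra_set(
    c(9000.5, 7000.25, 5000),
    matrix(c(pi, exp(1), sqrt(2), 1 / 3, 2 / 7, 1e-8), 2, 3, byrow = TRUE),
    c("a", "b")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  s2 <- load_spectra(path)
  expect_identical(s2$wavenumbers, s$wavenumbers)
  expect_identical(s2$absorbance, s$absorbance)
  expect_identical(s2$sample_ids, s$sample_ids)
})

test_that("loader validates shape, numerics and id uniqueness", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,9000,8000,7000", "a,1,2,3", "b,4,5,6"), path)
  s <- load_spectra(path)
  expect_equal(dim(s), c(2L, 3L))

  # ascending axis is canonicalised to descending, data reversed with it
  writeLines(c("sample_id,7000,8000,9000", "a,3,2,1"), path)
  expect_message(s2 <- load_spectra(path), "reversing")
  expect_equal(s2$wavenumbers, c(9000, 8000, 7000))
  expect_equal(unname(s2$absorbance[1, ]), c(1, 2, 3))

  writeLines(c("sample_id,9000,8000", "a,1,2", "a,3,4"), path)
  expect_error(load_spectra(path), "duplicate sample_id: a")
  writeLines(c("sample_id,9000,8000", "a,1"), path)
  expect_error(load_spectra(path), "ragged row 2")
  writeLines(c("sample_id,9000,8000", "a,1,oops"), path)
  expect_error(load_spectra(path), "non-numeric cell in row 2")
  writeLines(c("sample_id,11000,8000", "a,1,2"), path)
  expect_error(load_spectra(path, expected_range = c(10000, 4000)), "outside expected range")
})

test_that("replicate averaging equals the elementwise mean", {
  reps <- spectra_set(
    c(9000, 8000, 7000),
    rbind(c(0, 0, 0), c(2, 2, 2), c(1, 5, 9)),
    c("s1_r1", "s1_r2", "s1_r3")
  )
  avg <- average_replicates(reps, list(s1 = c("s1_r1", "s1_r2", "s1_r3")))
  expect_equal(unname(avg$absorbance[1, ]), c(1, 7 / 3, 11 / 3))

  # idempotence on identical replicates
  same <- average_replicates(reps, list(s = c("s1_r2", "s1_r2")))
  expect_equal(unname(same$absorbance[1, ]), c(2, 2, 2))

  # random replicates against a brute-force elementwise mean
  m <- seeded_matrix(3, 5, seed = 21)
  r3 <- spectra_set(seq(9000, 5000, length.out = 5), m, c("r1", "r2", "r3"))
  avg3 <- average_replicates(r3, list(s = c("r1", "r2", "r3")))
  brute <- (m[1, ] + m[2, ] + m[3, ]) / 3
  expect_equal(unname(avg3$absorbance[1, ]), brute)

  expect_error(average_replicates(reps, list(s = c("s1_r1", "nope"))), "missing replicate")
})

test_that("alignment inner-joins on sample id preserving spectra order", {
  s <- spectra_set(c(9000, 8000), rbind(c(1, 2), c(3, 4), c(5, 6)), c("a", "b", "c"))
  h <- data.frame(
    sample_id = c("c", "x", "a", "b"), batch_day = 1,
    F1 = c(3, 9, 1, 2), F2 = c(6, 9, 4, 5)
  )
  j <- align_spectra_hardness(s, h)
  expect_identical(j$spectra$sample_ids, c("a", "b", "c"))
  expect_identical(j$hardness$F1, c(1, 2, 3)) # reordered to spectra order
  expect_identical(j$dropped, "x")
  expect_error(
    align_spectra_hardness(s, data.frame(sample_id = "zz", F1 = 1, F2 = 2)),
    "no sample ids in common"
  )
})

test_that("decimation keeps every k-th wavenumber starting at the first", {
  s <- spectra_set(seq(9000, 8000, by = -100), matrix(1:22, 2, 11), c("a", "b"))
  d <- decimate_spectra(s, 4)
  expect_equal(d$wavenumbers, c(9000, 8600, 8200))
})

test_that("wavenumber-to-nm conversion is the reciprocal scale", {
  expect_equal(wavenumber_to_nm(10000), 1000)
  expect_equal(wavenumber_to_nm(4000), 2500)
})
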