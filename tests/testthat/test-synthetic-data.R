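test_that("generated hardness is range-calibrated and reproducible", {
  d1 <- generate_spectra(small_config(), curves = FALSE)
  d2 <- generate_spectra(small_config(), curves = FALSE)
  expect_identical(d1$spectra$absorbance, d2$spectra$absorbance)
  expect_identical(d1$hardness, d2$hardness)

  h <- d1$hardness
  expect_true(min(h$F1) >= 0.881 && max(h$F1) <= 3.721)
  expect_true(min(h$F2) >= 2.524 && max(h$F2) <= 4.201)
  expect_identical(nrow(h), nrow(d1$spectra$absorbance))
  expect_true(all(d1$truth$band_indices >= 1 &
    d1$truth$band_indices <= length(d1$spectra$wavenumbers)))

  # full-size default: printed Table-1-style bounds and documented mean band
  dd <- generate_spectra(synthetic_config(), curves = FALSE)
  expect_true(min(dd$hardness$F1) >= 0.881 && max(dd$hardness$F1) <= 3.721)
  expect_true(min(dd$hardness$F2) >= 2.524 && max(dd$hardness$F2) <= 4.201)
  expect_lt(abs(mean(dd$hardness$F1) - 1.583), 0.4)
  # storage trend: batch-mean F2 declines monotonically
  expect_true(all(diff(tapply(dd$hardness$F2, dd$hardness$batch, mean)) < 0))
})

test_that("noiseless single-factor model links hardness to band absorbance exactly", {
  cfg <- synthetic_config(
    n_samples = 24, n_batches = 6, wavenumber_step = 25,
    band_centers = 7000, band_widths = 100, band_factor = 1L,
    band_log_mean = log(0.5), band_log_trend = -0.3, band_log_sd = 0.3,
    band_wobble_sd = 0, band_log_uptick = 0,
    link_f1 = 1, link_f2 = 1,
    noise_sd = 0, baseline_drift_sd = 0, hardness_noise_sd = 0, seed = 3
  )
  d <- generate_spectra(cfg, curves = FALSE)
  peak <- d$spectra$absorbance[, d$truth$band_indices]
  expect_equal(abs(cor(d$hardness$F1, peak)), 1, tolerance = 1e-12)
})

test_that("planted link is exactly recoverable by OLS when all noise is off", {
  cfg <- small_config(
    seed = 5, noise_sd = 0, baseline_drift_sd = 0,
    hardness_noise_sd = 0
  )
  d <- generate_spectra(cfg, curves = FALSE)
  A <- d$spectra$absorbance[, d$truth$band_indices]
  fit <- lm(d$hardness$F1 ~ A)
  expect_lt(sum(residuals(fit)^2), 1e-20)
})

test_that("puncture curves carry the planted peaks and a sub-peak plateau", {
  # representative day-1 magnitudes; zero jitter recovers them exactly
  pk <- summarize_sample(generate_puncture_curves(1.53, 4.109, jitter = 0, seed = 1))
  expect_identical(unname(pk), c(1.53, 4.109))

  # default jitter: 6-curve mean within 2% of planted values
  for (s in c(1, 2, 3)) {
    pk <- summarize_sample(generate_puncture_curves(1.53, 4.109, jitter = 0.01, seed = s))
    expect_true(all(abs(pk / c(1.53, 4.109) - 1) < 0.02))
  }

  # plateau region stays strictly below the second peak
  cur <- generate_puncture_curves(2, 3.5, jitter = 0, seed = 1)[[1]]
  plateau <- cur$force_gN[cur$displacement_mm > 5]
  expect_true(max(plateau) < 3.5)

  expect_error(generate_puncture_curves(-1, 2), "positive")
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(band_widths = c(1, 2)), "length")
  expect_error(synthetic_config(n_samples = 121), "divisible")
  expect_error(
    synthetic_config(wavenumber_start = 4000, wavenumber_stop = 10000),
    "descend"
  )
  expect_error(synthetic_config(band_centers = c(8403, 6896, 5154, 7142, 200)),
    "inside"
  )
})
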