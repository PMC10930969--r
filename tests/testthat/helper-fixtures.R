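# Small fixtures built in code; all seeded.

# compact synthetic dataset: 48 fruits, 121-point axis (50 cm-1 spacing)
small_config <- function(seed = 11, ...) {
  synthetic_config(
    n_samples = 48L, n_batches = 6L,
    wavenumber_step = 50, seed = seed, ...
  )
}

seeded_matrix <- function(n, p, seed, sd = 1) {
  epinir:::with_seed(seed, matrix(stats::rnorm(n * p, sd = sd), n, p))
}

seeded_vector <- function(n, seed, sd = 1) {
  epinir:::with_seed(seed, stats::rnorm(n, sd = sd))
}

# calibration-side matrix + response carved from a small synthetic dataset,
# mean-centred (the setting the selectors operate in)
small_calibration <- function(seed = 11, response = "F1") {
  d <- generate_spectra(small_config(seed), curves = FALSE)
  y <- d$hardness[[response]]
  split <- spxy_split(d$spectra, y, 0.75)
  cal <- match(split$calibration_ids, d$hardness$sample_id)
  state <- preprocess_fit("MC", d$spectra[split$calibration_ids, ])
  list(
    X = preprocess_apply(state, d$spectra[split$calibration_ids, ])$absorbance,
    y = y[cal],
    wavenumbers = d$spectra$wavenumbers,
    dataset = d,
    split = split
  )
}
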