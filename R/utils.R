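#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from one master seed. Each stage draws
#' its own sub-seed by hashing the master seed together with a stage tag, so
#' stages can be re-run independently and still reproduce exactly.
#'
#' @param seed master integer seed.
#' @param tag character label of the random stream (e.g. `"spectra"`,
#'   `"cars/F1"`).
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime: keeps the result a valid R integer
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1L) + 1)
}

#' Run an expression under a local RNG state
#'
#' Evaluates `expr` with the RNG seeded to `seed`, then restores the caller's
#' RNG state so library code never perturbs user-level randomness.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Convert wavenumber (cm-1) to wavelength (nm)
#'
#' Display helper only; all selections are stored as indices into the
#' wavenumber axis.
#'
#' @param wavenumber numeric vector in cm-1.
#' @return wavelength in nm (`1e7 / wavenumber`).
#' @export
wavenumber_to_nm <- function(wavenumber) {
  stopifnot(is.numeric(wavenumber), all(wavenumber > 0))
  1e7 / wavenumber
}

# Deterministic k-fold assignment, stratified on y: samples are ranked by y
# and dealt round-robin into folds, so every fold spans the response range and
# the assignment contains no RNG (used where an operation must be fully
# deterministic, e.g. SPA subset scoring).
stratified_folds <- function(y, k) {
  stopifnot(k >= 2, length(y) >= k)
  fold <- integer(length(y))
  fold[order(y, seq_along(y))] <- rep_len(seq_len(k), length(y))
  fold
}

# Seeded k-fold assignment shared by all candidates inside one fit, so model
# comparisons are paired.
seeded_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}
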