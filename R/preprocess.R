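#' Moving-average spectral smoothing
#'
#' Replaces the absorbance at each wavelength point by the mean of the
#' `(2w + 1)`-point window centred on it; at the edges the window shrinks to
#' the available points so the output length is unchanged and no edge NaNs
#' appear. Smoothing is along the wavelength axis.
#'
#' @param x numeric vector (one spectrum) or matrix / [spectra_set()]
#'   (samples in rows).
#' @param w window half-width (window size `2w + 1`); must be `>= 1`. The
#'   package default of `w = 3` (7-point window) is a mild smoother chosen
#'   for 1 cm-1-spaced spectra.
#' @return same shape/class as `x`, smoothed.
#' @export
moving_average <- function(x, w = 3L) {
  if (!is.numeric(w) || length(w) != 1L || w < 1) {
    stop("window half-width w must be a positive integer", call. = FALSE)
  }
  w <- as.integer(w)
  if (inherits(x, "spectra_set")) {
    return(spectra_set(
      x$wavenumbers, moving_average(x$absorbance, w),
      x$sample_ids
    ))
  }
  if (is.matrix(x)) {
    return(t(apply(x, 1L, ma_vector, w = w)))
  }
  ma_vector(x, w)
}

ma_vector <- function(x, w) {
  n <- length(x)
  if (2L * w + 1L > n) {
    stop("window 2w+1 = ", 2L * w + 1L, " exceeds spectrum length ", n,
      call. = FALSE
    )
  }
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - w, 1L)
  hi <- pmin(seq_len(n) + w, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fit / apply preprocessing on the calibration set
#'
#' `preprocess_fit()` learns any state from the calibration spectra only;
#' `preprocess_apply()` applies that state to arbitrary spectra (calibration
#' or prediction), so no prediction-set statistic can leak into a fit.
#'
#' Methods: `"none"` (identity), `"MA"` (moving average, stateless beyond the
#' window), `"MC"` (mean centering: subtract the calibration-set mean
#' spectrum).
#'
#' @param method `"none"`, `"MA"` or `"MC"`.
#' @param calibration a [spectra_set()] of calibration samples.
#' @param w moving-average half-width (MA only).
#' @return `preprocess_fit()`: a `preprocess_state`; `preprocess_apply()`:
#'   a `spectra_set`.
#' @export
preprocess_fit <- function(method = c("none", "MA", "MC"), calibration,
                           w = 3L) {
  method <- match.arg(method)
  stopifnot(inherits(calibration, "spectra_set"))
  state <- list(method = method, w = w, mean_spectrum = NULL)
  if (method == "MC") {
    state$mean_spectrum <- colMeans(calibration$absorbance)
  }
  structure(state, class = "preprocess_state")
}

#' @param state a `preprocess_state` from `preprocess_fit()`.
#' @param spectra a [spectra_set()] to transform.
#' @rdname preprocess_fit
#' @export
preprocess_apply <- function(state, spectra) {
  if (!inherits(state, "preprocess_state")) {
    stop("state error: preprocess_apply() requires a state from preprocess_fit()",
      call. = FALSE
    )
  }
  stopifnot(inherits(spectra, "spectra_set"))
  switch(state$method,
    none = spectra,
    MA = moving_average(spectra, state$w),
    MC = {
      if (length(state$mean_spectrum) != length(spectra$wavenumbers)) {
        stop("mean spectrum length does not match wavenumber axis", call. = FALSE)
      }
      spectra_set(
        spectra$wavenumbers,
        sweep(spectra$absorbance, 2L, state$mean_spectrum),
        spectra$sample_ids
      )
    }
  )
}

#' Mean-centering convenience wrappers
#'
#' Thin wrappers over [preprocess_fit()]/[preprocess_apply()] with
#' `method = "MC"`.
#'
#' @inheritParams preprocess_fit
#' @export
mean_center_fit <- function(calibration) preprocess_fit("MC", calibration)

#' @rdname mean_center_fit
#' @inheritParams preprocess_apply
#' @export
mean_center_apply <- function(state, spectra) preprocess_apply(state, spectra)
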