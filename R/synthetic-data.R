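#' Configuration of the synthetic passion-fruit dataset
#'
#' The generator emulates the statistical structure of the study design: 120
#' fruits sampled in 6 storage batches (one batch every three days), NIR
#' absorbance over 10,000-4000 cm-1 at 1 cm-1 spacing (6001 points), with
#' Gaussian absorption bands at the water (8403, 6896, 5154 cm-1), cellulose
#' (7142 cm-1) and pectin (4464 cm-1) positions. Per-sample band amplitudes
#' are log-normal latent concentrations that decay with storage batch (water
#' loss); outer (F1) and inner (F2) epicarp hardness are affine functions of
#' those concentrations, min-max rescaled into the configured gN ranges.
#'
#' F1's latent driver (pectin) carries the largest log-scale spread, giving
#' the right-skewed F1 distribution seen in the study (mean well below the
#' range midpoint), plus a final-batch uptick; F2 is water-dominated and
#' declines near-linearly across batches.
#'
#' Bands belonging to one constituent share a latent factor: the three water
#' overtone bands rise and fall together (the same underlying water
#' content), with a small per-band independent wobble on top, so
#' response-extreme fruits are also spectrally extreme — the coupling that
#' joint X-Y partitioning and wavelength selection exploit on real spectra.
#'
#' @param n_samples total fruits (divisible by `n_batches`).
#' @param n_batches storage batches; batch `b` is storage day `3(b-1)+1`.
#' @param wavenumber_start,wavenumber_stop,wavenumber_step axis in cm-1
#'   (descending from start to stop).
#' @param band_centers,band_widths Gaussian band positions and sigmas (cm-1),
#'   equal length.
#' @param band_factor integer constituent index per band (bands sharing a
#'   factor share one latent concentration draw per sample; default: bands
#'   1-3 water, 4 cellulose, 5 pectin).
#' @param band_log_mean,band_log_trend,band_log_sd per-band log-normal latent
#'   parameters: baseline log amplitude, log change from first to last batch,
#'   and per-sample log spread (loading on the shared factor draw).
#' @param band_wobble_sd per-band independent log wobble on top of the shared
#'   factor (band-specific variation not shared by the constituent).
#' @param band_log_uptick per-band log bump applied in the final batch only.
#' @param link_f1,link_f2 unitless weights mapping latent concentrations to
#'   the raw F1/F2 scores.
#' @param noise_sd i.i.d. absorbance noise (AU).
#' @param baseline_drift_sd sd of the per-sample quadratic baseline
#'   coefficients (AU).
#' @param hardness_noise_sd sd of the additive noise on raw hardness scores
#'   (pre-rescaling, score units).
#' @param f1_range,f2_range target gN intervals for the rescaled responses.
#' @param curve_jitter multiplicative sd of per-curve peak jitter in the
#'   puncture-curve generator.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 120L,
                             n_batches = 6L,
                             wavenumber_start = 10000,
                             wavenumber_stop = 4000,
                             wavenumber_step = 1,
                             band_centers = c(8403, 6896, 5154, 7142, 4464),
                             band_widths = c(90, 80, 90, 70, 50),
                             band_factor = c(1L, 1L, 1L, 2L, 3L),
                             band_log_mean = log(c(0.8, 0.7, 0.9, 0.35, 0.30)),
                             band_log_trend = c(-0.55, -0.50, -0.60, -0.15, -0.30),
                             band_log_sd = c(0.15, 0.15, 0.15, 0.10, 0.55),
                             band_wobble_sd = c(0.10, 0.10, 0.10, 0.08, 0.08),
                             band_log_uptick = c(0, 0, 0, 0, 0.35),
                             link_f1 = c(0.50, 0.50, 0.50, 0.50, 1.00),
                             link_f2 = c(1.00, 1.00, 1.00, 0.45, 0.35),
                             noise_sd = 0.004,
                             baseline_drift_sd = 0.01,
                             hardness_noise_sd = 0.01,
                             f1_range = c(0.881, 3.721),
                             f2_range = c(2.524, 4.201),
                             curve_jitter = 0.01,
                             seed = 42L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_batches = as.integer(n_batches),
    wavenumber_start = wavenumber_start, wavenumber_stop = wavenumber_stop,
    wavenumber_step = wavenumber_step,
    band_centers = band_centers, band_widths = band_widths,
    band_factor = as.integer(band_factor),
    band_log_mean = band_log_mean, band_log_trend = band_log_trend,
    band_log_sd = band_log_sd, band_wobble_sd = band_wobble_sd,
    band_log_uptick = band_log_uptick,
    link_f1 = link_f1, link_f2 = link_f2,
    noise_sd = noise_sd, baseline_drift_sd = baseline_drift_sd,
    hardness_noise_sd = hardness_noise_sd,
    f1_range = f1_range, f2_range = f2_range,
    curve_jitter = curve_jitter, seed = as.integer(seed)
  )
  k <- length(cfg$band_centers)
  per_band <- c(
    "band_widths", "band_factor", "band_log_mean", "band_log_trend",
    "band_log_sd", "band_wobble_sd", "band_log_uptick", "link_f1", "link_f2"
  )
  for (f in per_band) {
    if (length(cfg[[f]]) != k) {
      stop("configuration error: ", f, " must have length ", k,
        " (one per band center)",
        call. = FALSE
      )
    }
  }
  if (cfg$wavenumber_start <= cfg$wavenumber_stop || cfg$wavenumber_step <= 0) {
    stop("configuration error: wavenumber axis must descend from start to stop",
      call. = FALSE
    )
  }
  if (any(cfg$band_centers > cfg$wavenumber_start |
    cfg$band_centers < cfg$wavenumber_stop)) {
    stop("configuration error: band centers must lie inside the wavenumber range",
      call. = FALSE
    )
  }
  if (cfg$n_samples %% cfg$n_batches != 0L) {
    stop("configuration error: n_samples must be divisible by n_batches",
      call. = FALSE
    )
  }
  if (diff(cfg$f1_range) <= 0 || diff(cfg$f2_range) <= 0) {
    stop("configuration error: hardness ranges must be increasing intervals",
      call. = FALSE
    )
  }
  structure(cfg, class = "synthetic_config")
}

# min-max map of raw scores onto [lo, hi]; endpoints are attained exactly
rescale_to_range <- function(s, range) {
  if (max(s) == min(s)) stop("degenerate raw hardness scores", call. = FALSE)
  range[1] + (s - min(s)) / (max(s) - min(s)) * diff(range)
}

#' Generate a synthetic spectra + hardness + puncture-curve dataset
#'
#' @param config a [synthetic_config()].
#' @param curves if `FALSE`, skip puncture-curve generation (spectra and
#'   hardness only; faster for model-focused runs).
#' @return a list of class `synthetic_dataset`: `spectra` (a
#'   [spectra_set()]), `hardness` (data frame `sample_id`, `batch`,
#'   `batch_day`, `F1`, `F2`), `curves` (per-sample list of 6 puncture
#'   curves, or `NULL`), and `truth` (planted band indices, latent
#'   concentrations and link weights).
#' @export
generate_spectra <- function(config = synthetic_config(), curves = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  nb <- config$n_batches
  wn <- seq(config$wavenumber_start, config$wavenumber_stop,
    by = -config$wavenumber_step
  )
  k <- length(config$band_centers)
  batch <- rep(seq_len(nb), each = n / nb)
  tfrac <- (batch - 1) / (nb - 1)
  last <- as.numeric(batch == nb)

  conc <- with_seed(derive_seed(config$seed, "latent"), {
    nf <- max(config$band_factor)
    zf <- matrix(stats::rnorm(n * nf), n, nf) # shared constituent draws
    zb <- matrix(stats::rnorm(n * k), n, k) # per-band wobble
    z <- zf[, config$band_factor, drop = FALSE]
    logc <- sweep(z, 2, config$band_log_sd, `*`) +
      sweep(zb, 2, config$band_wobble_sd, `*`)
    logc <- sweep(logc, 2, config$band_log_mean, `+`) +
      outer(tfrac, config$band_log_trend) +
      outer(last, config$band_log_uptick)
    exp(logc)
  })

  # Gaussian band shapes: profile[k, ] is unit-amplitude absorbance of band k
  profile <- t(vapply(seq_len(k), function(j) {
    exp(-(wn - config$band_centers[j])^2 / (2 * config$band_widths[j]^2))
  }, numeric(length(wn))))
  absorb <- conc %*% profile

  if (config$baseline_drift_sd > 0) {
    u <- (wn - mean(wn)) / (max(wn) - min(wn)) # in [-0.5, 0.5]
    base_coef <- with_seed(
      derive_seed(config$seed, "baseline"),
      matrix(stats::rnorm(n * 3, sd = config$baseline_drift_sd), n, 3)
    )
    absorb <- absorb + base_coef %*% rbind(rep(1, length(wn)), u, u^2)
  }
  if (config$noise_sd > 0) {
    absorb <- absorb + with_seed(
      derive_seed(config$seed, "noise"),
      matrix(stats::rnorm(n * length(wn), sd = config$noise_sd), n, length(wn))
    )
  }

  eps <- with_seed(
    derive_seed(config$seed, "hardness"),
    matrix(stats::rnorm(n * 2, sd = config$hardness_noise_sd), n, 2)
  )
  s1 <- drop(conc %*% config$link_f1) + eps[, 1]
  s2 <- drop(conc %*% config$link_f2) + eps[, 2]
  f1 <- rescale_to_range(s1, config$f1_range)
  f2 <- rescale_to_range(s2, config$f2_range)

  ids <- sprintf("S%03d", seq_len(n))
  hardness <- data.frame(
    sample_id = ids, batch = batch, batch_day = 3L * (batch - 1L) + 1L,
    F1 = f1, F2 = f2, stringsAsFactors = FALSE
  )

  curve_list <- NULL
  if (isTRUE(curves)) {
    curve_list <- lapply(seq_len(n), function(i) {
      generate_puncture_curves(f1[i], f2[i],
        jitter = config$curve_jitter,
        seed = derive_seed(config$seed, paste0("curves/", ids[i]))
      )
    })
    names(curve_list) <- ids
  }

  structure(
    list(
      spectra = spectra_set(wn, absorb, ids),
      hardness = hardness,
      curves = curve_list,
      truth = list(
        band_indices = vapply(
          config$band_centers,
          function(b) which.min(abs(wn - b)), integer(1)
        ),
        band_centers = config$band_centers,
        concentrations = conc,
        link_f1 = config$link_f1,
        link_f2 = config$link_f2
      ),
      config = config
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(
    "<synthetic_dataset> ", x$config$n_samples, " samples, ",
    length(x$spectra$wavenumbers), " wavenumbers, ",
    x$config$n_batches, " storage batches\n",
    sep = ""
  )
  invisible(x)
}

#' Generate replicate puncture curves for one fruit
#'
#' Produces `n_curves` force-displacement traces over 0-10 mm, each with a
#' first local maximum at the planted outer-epicarp force `f1` (shallow
#' displacement), a second at the inner-epicarp force `f2`, then a gently
#' declining sponge plateau strictly below `f2` (the mesocarp phase). Curves
#' are piecewise linear through jittered knots, with the knots included in
#' the displacement grid so that at `jitter = 0` the planted peaks are
#' recovered exactly by peak extraction.
#'
#' @param f1,f2 planted peak forces in gN (`> 0`).
#' @param n_curves replicate punctures per fruit (6 in the study protocol).
#' @param jitter multiplicative sd of per-curve peak perturbation.
#' @param seed integer seed.
#' @return list of `n_curves` data frames (`displacement_mm`, `force_gN`).
#' @export
generate_puncture_curves <- function(f1, f2, n_curves = 6L, jitter = 0.01,
                                     seed = 1L) {
  if (!is.numeric(f1) || !is.numeric(f2) || f1 <= 0 || f2 <= 0) {
    stop("peak forces f1 and f2 must be positive", call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_curves), function(cc) {
      j1 <- 1 + jitter * stats::rnorm(1)
      j2 <- 1 + jitter * stats::rnorm(1)
      dip <- 0.55 * min(f1 * j1, f2 * j2)
      knot_d <- c(0, 0.8, 1.8, 3.2, 4.4, 10)
      if (jitter > 0) {
        knot_d[2:5] <- knot_d[2:5] * (1 + 0.03 * jitter / 0.01 * stats::runif(4, -1, 1))
      }
      knot_f <- c(0, f1 * j1, dip, f2 * j2, 0.72 * f2 * j2, 0.66 * f2 * j2)
      d <- sort(unique(c(seq(0, 10, by = 0.02), knot_d)))
      data.frame(
        displacement_mm = d,
        force_gN = stats::approx(knot_d, knot_f, xout = d)$y
      )
    })
  })
}

#' Write per-sample puncture curves as CSVs
#'
#' One file per curve, named `<sample_id>_curve<j>.csv`, columns
#' `displacement_mm`, `force_gN`.
#'
#' @param curves per-sample list of curve lists, as in a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_puncture_curves <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(curves)) {
    for (j in seq_along(curves[[id]])) {
      utils::write.csv(curves[[id]][[j]],
        file.path(dir, sprintf("%s_curve%d.csv", id, j)),
        row.names = FALSE, quote = FALSE
      )
    }
  }
  invisible(dir)
}
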