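#' Normalised CARS importance weights
#'
#' `w_i = |b_i| / sum(|b_i|)` over the PLS regression coefficients of the
#' variables in play; the weights sum to one exactly.
#'
#' @param b numeric vector of PLS regression coefficients.
#' @return numeric vector of weights summing to 1.
#' @export
cars_weights <- function(b) {
  s <- sum(abs(b))
  if (s == 0) stop("degenerate: all regression coefficients are zero", call. = FALSE)
  abs(b) / s
}

#' UVE stability of coefficient trajectories
#'
#' `h_i = mean(b_i) / sd(b_i)` column-wise over a matrix of resampled
#' regression coefficients (sample sd, n-1 denominator). A zero sd yields
#' `+/-Inf` ("perfectly stable") with a warning.
#'
#' @param B numeric matrix, one row per resample, one column per variable.
#' @return numeric stability vector, one per column.
#' @export
uve_stability <- function(B) {
  B <- as.matrix(B)
  m <- colMeans(B)
  s <- apply(B, 2L, stats::sd)
  if (any(s == 0)) {
    warning("zero coefficient sd for ", sum(s == 0),
      " variable(s); stability set to +/-Inf",
      call. = FALSE
    )
  }
  ifelse(s == 0, sign(m) * Inf, m / s)
}

selection_result <- function(method, selected, wavenumbers = NULL,
                             diagnostics = list(), cv_rmse_path = NULL) {
  selected <- sort(unique(as.integer(selected)))
  structure(
    list(
      method = method,
      selected = selected,
      wavenumbers = if (!is.null(wavenumbers)) wavenumbers[selected],
      diagnostics = diagnostics,
      cv_rmse_path = cv_rmse_path
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$method, ": ", length(x$selected),
    " wavelengths selected\n",
    sep = ""
  )
  invisible(x)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Runs `n_mc_runs` Monte-Carlo iterations. Each iteration (i) fits a PLS
#' model on a random subsample of the calibration samples using the
#' currently surviving variables, (ii) converts the coefficients to
#' normalised weights `w_i = |b_i|/sum|b_i|`, (iii) enforces the
#' exponentially decreasing retention schedule (all variables survive the
#' first iteration, two survive the last) by keeping the top-weighted
#' variables, and (iv) applies adaptive reweighted sampling — a weighted
#' bootstrap among the survivors with inclusion probability proportional to
#' weight. Every iteration's subset is scored by k-fold cross-validated PLS
#' RMSE on the full calibration set; the returned subset is the smallest one
#' whose RMSECV is within `rmse_tol` (relative) of the minimum over all
#' iterations (`rmse_tol = 0` returns the strict RMSECV argmin).
#'
#' @param X calibration predictor matrix (preprocessed spectra, samples in
#'   rows). Calibration data only.
#' @param y calibration response.
#' @param n_mc_runs Monte-Carlo iterations (default 50).
#' @param subsample fraction of samples drawn (without replacement) per
#'   iteration (default 0.8); `1` disables subsampling.
#' @param n_components PLS components; `NULL` selects by CV once on the full
#'   matrix (capped at 10).
#' @param k_folds folds for subset scoring.
#' @param schedule optional integer vector of length `n_mc_runs` overriding
#'   the exponential retention counts.
#' @param ars apply the adaptive reweighted sampling step (default `TRUE`);
#'   with `FALSE` each iteration reduces to top-weight thresholding.
#' @param rmse_tol relative RMSECV tolerance of the parsimony rule for
#'   picking the winning iteration (default 0.02).
#' @param min_vars smallest subset size kept (default 2).
#' @param seed integer seed for subsampling and ARS.
#' @param wavenumbers optional axis for labelling the selection.
#' @return a `selection_result` with diagnostics `weights` (per-variable
#'   weights at the winning iteration, named by variable index),
#'   `n_vars_path` and `cv_rmse_path`.
#' @export
cars_select <- function(X, y, n_mc_runs = 50L, subsample = 0.8,
                        n_components = NULL, k_folds = 5L, schedule = NULL,
                        ars = TRUE, rmse_tol = 0.02, min_vars = 2L, seed = 1L,
                        wavenumbers = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(n_mc_runs >= 1L, subsample > 0, subsample <= 1)
  if (is.null(n_components)) n_components <- pls_select_ncomp(X, y, k_folds = k_folds)

  if (is.null(schedule)) {
    # two-parameter exponential decay r_i = a e^{-k i}: all p variables at
    # i = 1, two variables at i = N
    if (n_mc_runs == 1L) {
      schedule <- p
    } else {
      kk <- log(p / 2) / (n_mc_runs - 1L)
      a <- exp(kk)
      schedule <- pmax(min_vars, pmin(p, round(p * a * exp(-kk * seq_len(n_mc_runs)))))
    }
  }
  if (length(schedule) != n_mc_runs) {
    stop("schedule length must equal n_mc_runs", call. = FALSE)
  }

  survivors <- seq_len(p)
  subsets <- vector("list", n_mc_runs)
  weight_list <- vector("list", n_mc_runs)
  rmse_path <- numeric(n_mc_runs)

  with_seed(derive_seed(seed, "cars"), {
    for (i in seq_len(n_mc_runs)) {
      rows <- if (subsample < 1) {
        sample(n, max(2L, round(subsample * n)))
      } else {
        seq_len(n)
      }
      ncmp <- min(n_components, length(rows) - 1L, length(survivors))
      fit <- pls_fit(X[rows, survivors, drop = FALSE], y[rows], ncmp)
      w <- cars_weights(fit$coefficients)
      names(w) <- as.character(survivors)

      m <- min(schedule[i], length(survivors))
      keep <- survivors[order(w, decreasing = TRUE)[seq_len(m)]]
      if (ars && length(keep) > min_vars) {
        wk <- w[as.character(keep)]
        keep <- unique(sample(keep, size = m, replace = TRUE, prob = wk))
        if (length(keep) < min_vars) {
          keep <- survivors[order(w, decreasing = TRUE)[seq_len(min_vars)]]
        }
      }
      survivors <- sort(keep)
      subsets[[i]] <- survivors
      weight_list[[i]] <- w
      rmse_path[i] <- pls_cv_rmse(
        X[, survivors, drop = FALSE], y,
        min(n_components, length(survivors)), k_folds
      )
    }
  })

  # parsimony rule: subsets shrink over iterations, so the last iteration
  # within tolerance of the global minimum is the smallest qualifying subset
  ok <- which(rmse_path <= min(rmse_path) * (1 + rmse_tol))
  best <- ok[length(ok)]
  selection_result(
    "CARS", subsets[[best]], wavenumbers,
    diagnostics = list(
      weights = weight_list[[best]],
      n_vars_path = lengths(subsets),
      best_iteration = best,
      n_components = n_components
    ),
    cv_rmse_path = rmse_path
  )
}

# Grow one SPA chain from a starting column: repeatedly project all columns
# onto the orthogonal complement of the selected set and add the column of
# maximal residual norm. Zero-residual (collinear) columns are skipped with
# a warning. Returns the integer chain in selection order, or NULL for a
# zero-norm start.
spa_build_chain <- function(Xc, norm2, tol, s0, k_max) {
  if (norm2[s0] <= tol) {
    return(NULL)
  }
  chain <- s0
  Q <- Xc[, s0, drop = FALSE] / sqrt(norm2[s0])
  res2 <- norm2 - as.vector(crossprod(Xc, Q))^2
  while (length(chain) < k_max) {
    res2[chain] <- -Inf
    zero <- res2 <= tol & is.finite(res2)
    if (any(zero)) {
      warning("SPA: skipping ", sum(zero),
        " column(s) with zero residual norm",
        call. = FALSE
      )
      res2[zero] <- -Inf
    }
    if (all(!is.finite(res2))) break
    pick <- which.max(res2)
    r <- Xc[, pick] - Q %*% crossprod(Q, Xc[, pick])
    nr <- sqrt(sum(r^2))
    if (nr^2 <= tol) break
    Q <- cbind(Q, r / nr)
    chain <- c(chain, pick)
    res2 <- norm2 - colSums(crossprod(Q, Xc)^2)
  }
  as.integer(chain)
}

# test hook: build one chain on raw X (centred internally) from a fixed start
spa_chain_for_test <- function(X, start, k) {
  Xc <- sweep(as.matrix(X), 2L, colMeans(X))
  norm2 <- colSums(Xc^2)
  spa_build_chain(Xc, norm2, max(norm2) * 1e-12, start, k)
}

#' Successive projections algorithm (SPA)
#'
#' Greedy selection of minimally collinear wavelengths. Starting from a
#' candidate column, the algorithm repeatedly projects every unselected
#' column onto the orthogonal complement of the selected set,
#' `p = x_j - x_k (x_k' x_j) / (x_k' x_k)` generalised to the running
#' subspace, and adds the column with the largest residual norm. Chains are
#' grown to `k_max` variables from each of the `n_starts` candidate starting
#' columns (those most correlated with the response, a deterministic
#' restriction that keeps the search tractable on dense spectral grids), and
#' the final (start, chain length) combination is the one minimising the
#' k-fold cross-validated RMSE of a multiple linear regression on the
#' subset. Fully deterministic: folds are rank-stratified and ties break to
#' the lowest index.
#'
#' @inheritParams cars_select
#' @param k_min,k_max chain-length range scored (defaults 2 and 15).
#' @param n_starts candidate starting columns (default 10).
#' @return a `selection_result` with diagnostics `start`, `chain`
#'   (selection order), `projection_norms` and per-length `cv_rmse_path`.
#' @export
spa_select <- function(X, y, k_min = 2L, k_max = 15L, n_starts = 10L,
                       k_folds = 5L, wavenumbers = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  k_max <- min(k_max, n - 2L, p)
  k_min <- min(k_min, k_max)
  stopifnot(k_min >= 1L, k_max >= k_min)

  Xc <- sweep(X, 2L, colMeans(X))
  norm2 <- colSums(Xc^2)
  tol <- max(norm2) * 1e-12
  sdy <- stats::sd(y)
  cory <- if (sdy == 0) rep(0, p) else {
    suppressWarnings(abs(as.vector(stats::cor(Xc, y))))
  }
  cory[!is.finite(cory)] <- 0
  starts <- order(cory, decreasing = TRUE)[seq_len(min(n_starts, p))]

  chains <- lapply(starts, function(s0) {
    spa_build_chain(Xc, norm2, tol, s0, k_max)
  })

  fold <- stratified_folds(y, min(k_folds, n))
  score_subset <- function(idx) {
    res <- numeric(n)
    for (f in unique(fold)) {
      hold <- fold == f
      Xf <- cbind(1, X[!hold, idx, drop = FALSE])
      cf <- tryCatch(qr.coef(qr(Xf), y[!hold]), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) {
        return(Inf)
      }
      res[hold] <- y[hold] - drop(cbind(1, X[hold, idx, drop = FALSE]) %*% cf)
    }
    sqrt(mean(res^2))
  }

  best <- list(rmse = Inf, chain = NULL, k = NA_integer_, start = NA_integer_)
  paths <- list()
  for (ci in seq_along(chains)) {
    chain <- chains[[ci]]
    if (is.null(chain) || length(chain) < k_min) next
    ks <- seq(k_min, min(k_max, length(chain)))
    rms <- vapply(ks, function(k) score_subset(chain[seq_len(k)]), numeric(1))
    paths[[as.character(starts[ci])]] <- stats::setNames(rms, ks)
    j <- which.min(rms)
    if (rms[j] < best$rmse) {
      best <- list(
        rmse = rms[j], chain = chain, k = ks[j], start = starts[ci]
      )
    }
  }
  if (is.null(best$chain)) stop("SPA found no scorable chain", call. = FALSE)

  sel <- best$chain[seq_len(best$k)]
  selection_result(
    "SPA", sel, wavenumbers,
    diagnostics = list(
      start = best$start,
      chain = sel, # in selection order
      candidate_starts = starts,
      cv_rmse_by_length = paths[[as.character(best$start)]]
    ),
    cv_rmse_path = paths[[as.character(best$start)]]
  )
}

#' Uninformative variable elimination (UVE)
#'
#' Appends an equal-width block of tiny uniform noise variables to the
#' calibration matrix, fits a PLS model under leave-one-out resampling of
#' the samples, and measures each variable's stability
#' `h_i = mean(b_i)/sd(b_i)` across the resampled coefficient trajectories.
#' The elimination threshold is the largest `|h|` observed in the noise
#' block: a real wavelength is kept only if its coefficient is more stable
#' than every known-uninformative variable. The noise amplitude (relative to
#' `max|X|`) is small enough not to perturb the fit yet nonzero so
#' coefficients vary.
#'
#' @inheritParams cars_select
#' @param noise_scale amplitude of the uniform noise block relative to
#'   `max(abs(X))` (default `1e-10`).
#' @return a `selection_result` (possibly empty when no variable beats the
#'   noise, e.g. for a pure-noise response) with diagnostics `stability`
#'   (length `2p`: real then noise block) and `threshold`.
#' @export
uve_select <- function(X, y, noise_scale = 1e-10, n_components = NULL,
                       seed = 1L, wavenumbers = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(noise_scale > 0)
  if (is.null(n_components)) {
    # conservative PLS dimension: stability analysis degrades when the model
    # carries near-noise components, so a wide parsimony tolerance is used
    n_components <- pls_select_ncomp(X, y, tol = 0.10)
  }
  noise <- with_seed(
    derive_seed(seed, "uve-noise"),
    matrix(stats::runif(n * p), n, p) * noise_scale * max(abs(X))
  )
  Z <- cbind(X, noise)
  B <- matrix(NA_real_, n, 2L * p)
  for (i in seq_len(n)) {
    ncmp <- min(n_components, n - 2L, 2L * p)
    fit <- pls_fit(Z[-i, , drop = FALSE], y[-i], ncmp)
    B[i, ] <- fit$coefficients
  }
  h <- uve_stability(B)
  threshold <- max(abs(h[(p + 1L):(2L * p)]))
  sel <- which(abs(h[seq_len(p)]) > threshold)
  selection_result(
    "UVE", sel, wavenumbers,
    diagnostics = list(
      stability = h, threshold = threshold,
      n_components = n_components
    )
  )
}

#' Count planted bands recovered by a selection
#'
#' A band is covered when at least one selected wavenumber lies within
#' `tol` cm-1 of its centre.
#'
#' @param selected_wavenumbers numeric vector of selected wavenumbers.
#' @param band_centers numeric band centres (cm-1).
#' @param tol half-width of the coverage window (default 50 cm-1).
#' @return integer count of covered bands.
#' @export
band_coverage <- function(selected_wavenumbers, band_centers, tol = 50) {
  sum(vapply(
    band_centers,
    function(b) any(abs(selected_wavenumbers - b) <= tol), logical(1)
  ))
}

#' Serialize / read a selection result as JSON
#'
#' @param selection a `selection_result`.
#' @param path JSON file.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(
      method = selection$method,
      selected = selection$selected,
      wavenumbers = selection$wavenumbers,
      cv_rmse_path = selection$cv_rmse_path
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection_result(x$method, x$selected,
    cv_rmse_path = x$cv_rmse_path
  )
}
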