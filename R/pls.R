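#' Partial least squares regression (SIMPLS, univariate response)
#'
#' The shared regression engine behind the three wavelength selectors. Fits a
#' univariate-response PLS model by the SIMPLS construction: successive
#' weight vectors maximise covariance with the response under orthogonality
#' of the score loadings, and the model collapses to a single coefficient
#' vector `b` per wavelength plus an intercept, so
#' `prediction = X %*% b + intercept`.
#'
#' With `n_components` equal to the rank of the centred predictor matrix the
#' fit coincides with ordinary least squares.
#'
#' @param X numeric matrix, samples in rows.
#' @param y numeric response vector.
#' @param n_components number of latent components, in
#'   `[1, min(n_samples - 1, n_wavelengths)]`. Components whose score norm
#'   underflows are dropped (deflation exhausted).
#' @return object of class `pls_model`: `coefficients` (length `ncol(X)`),
#'   `intercept`, `n_components` (actually used), `x_mean`, `y_mean`.
#' @export
pls_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("y length must equal nrow(X)", call. = FALSE)
  if (n_components < 1 || n_components > min(n - 1L, p)) {
    stop("n_components must lie in [1, min(n-1, p)] = [1, ", min(n - 1L, p),
      "]",
      call. = FALSE
    )
  }
  A <- as.integer(n_components)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  X0 <- sweep(X, 2L, x_mean)
  y0 <- y - y_mean

  s <- crossprod(X0, y0) # p x 1 covariance direction
  R <- matrix(0, p, A)
  Q <- numeric(A)
  V <- matrix(0, p, A)
  used <- 0L
  tol <- .Machine$double.eps^0.5
  for (a in seq_len(A)) {
    r <- s
    t <- X0 %*% r
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < tol * max(1, sqrt(sum(y0^2)))) break
    t <- t / nt
    r <- r / nt
    pa <- crossprod(X0, t)
    qa <- sum(y0 * t)
    v <- pa
    if (a > 1L) {
      v <- v - V[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1L), drop = FALSE], pa)
    }
    nv <- sqrt(sum(v^2))
    if (nv < tol) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    Q[a] <- qa
    V[, a] <- v
    used <- a
  }
  if (used == 0L) stop("degenerate fit: X carries no covariance with y", call. = FALSE)
  b <- drop(R[, seq_len(used), drop = FALSE] %*% Q[seq_len(used)])
  structure(
    list(
      coefficients = b,
      intercept = y_mean - sum(x_mean * b),
      n_components = used, x_mean = x_mean, y_mean = y_mean
    ),
    class = "pls_model"
  )
}

#' @param object a `pls_model`.
#' @param newdata numeric matrix with the same columns the model was fit on.
#' @param ... ignored.
#' @rdname pls_fit
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
      length(object$coefficients),
      call. = FALSE
    )
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

# k-fold cross-validated RMSE of a PLS fit on (X, y) at a given component
# count. Folds are deterministic (rank-stratified on y) so selector-internal
# scoring carries no RNG of its own.
pls_cv_rmse <- function(X, y, n_components, k_folds = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- min(k_folds, n)
  fold <- stratified_folds(y, k)
  res <- numeric(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    ncmp <- min(n_components, sum(!hold) - 1L, ncol(X))
    fit <- pls_fit(X[!hold, , drop = FALSE], y[!hold], ncmp)
    res[hold] <- y[hold] - predict(fit, X[hold, , drop = FALSE])
  }
  sqrt(mean(res^2))
}

#' Choose the PLS component count by cross-validation
#'
#' Scans `1:max_components` (capped at `min(n - 2, p)`) with deterministic
#' rank-stratified folds and returns the smallest count whose k-fold RMSECV
#' is within `tol` (relative) of the minimum — the parsimonious reading of
#' the CV curve, which guards against the coefficient instability of
#' needlessly high PLS dimensions. The cap of 10 components reflects the low
#' intrinsic dimensionality of smooth NIR spectra.
#'
#' @inheritParams pls_fit
#' @param max_components upper bound on the scan (default 10).
#' @param k_folds folds (default 5).
#' @param tol relative RMSECV tolerance for the parsimony rule (default
#'   0.02; `0` reproduces the strict argmin).
#' @return integer component count.
#' @export
pls_select_ncomp <- function(X, y, max_components = 10L, k_folds = 5L,
                             tol = 0.02) {
  X <- as.matrix(X)
  amax <- min(max_components, nrow(X) - 2L, ncol(X))
  if (amax < 1L) stop("too few samples/variables to cross-validate", call. = FALSE)
  rmse <- vapply(
    seq_len(amax),
    function(a) pls_cv_rmse(X, y, a, k_folds), numeric(1)
  )
  which(rmse <= min(rmse) * (1 + tol))[1L]
}
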