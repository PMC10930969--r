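#' Extract the first two peak forces from a puncture curve
#'
#' The needle-probe puncture of a passion fruit shows a first force peak when
#' the outer epicarp (P1) fractures and a second when the inner deep-purple
#' epicarp (P2) fractures, followed by a stable sponge phase through the
#' mesocarp. F1 and F2 are the forces at the first and second local maxima
#' (ordered by displacement, not height) whose prominence exceeds the
#' threshold; later peaks and the plateau are ignored.
#'
#' @param curve data frame with strictly increasing `displacement_mm` in
#'   `[0, 10]` and non-negative `force_gN` of equal length (the aliases
#'   `displacement`/`force` are accepted).
#' @param prominence minimum peak prominence in gN; if `NULL`, defaults to
#'   5% of the curve maximum (guards against sensor ripple).
#' @return named numeric vector `c(F1 = ..., F2 = ...)`.
#' @export
extract_peak_forces <- function(curve, prominence = NULL) {
  d <- curve[["displacement_mm"]] %||% curve[["displacement"]]
  f <- curve[["force_gN"]] %||% curve[["force"]]
  if (is.null(d) || is.null(f)) {
    stop("curve must have displacement and force columns", call. = FALSE)
  }
  if (length(d) != length(f)) stop("displacement/force length mismatch", call. = FALSE)
  if (any(diff(d) <= 0)) stop("displacement must be strictly increasing", call. = FALSE)
  if (min(d) < 0 || max(d) > 10) {
    stop("displacement must lie within [0, 10] mm", call. = FALSE)
  }
  if (any(f < 0)) stop("negative forces: remove baseline first", call. = FALSE)
  if (is.null(prominence)) prominence <- 0.05 * max(f)
  if (prominence <= 0) stop("prominence must be > 0", call. = FALSE)

  peaks <- find_peaks(f, prominence)
  if (length(peaks) < 2L) {
    stop(
      "peaks-not-found: ", length(peaks),
      " qualifying peak(s) found, need 2",
      call. = FALSE
    )
  }
  c(F1 = f[peaks[1L]], F2 = f[peaks[2L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Local maxima of y with at least the given prominence, in index order.
# A maximum may be a flat run; its first index is reported. Prominence is the
# drop from the peak to the higher of the two bracketing minima, where each
# side is scanned until a strictly higher point (or the boundary) is reached.
find_peaks <- function(y, prominence) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L # flat top
      if (j < n && y[j + 1L] < y[i]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  keep <- vapply(cand, function(p) {
    left <- y[seq_len(p)]
    hi <- which(left > y[p])
    lbase <- min(left[seq(if (length(hi)) max(hi) else 1L, p)])
    right <- y[p:n]
    hi <- which(right > y[p])
    rbase <- min(right[seq_len(if (length(hi)) min(hi) else length(right))])
    (y[p] - max(lbase, rbase)) >= prominence
  }, logical(1))
  cand[keep]
}

#' Average peak forces over a fruit's replicate puncture curves
#'
#' @param curves list of puncture curves (the study protocol uses 6
#'   equidistant equatorial punctures per fruit).
#' @param n_expected required number of curves (default 6).
#' @param prominence passed to [extract_peak_forces()].
#' @return named numeric vector `c(F1 = ..., F2 = ...)` of arithmetic means.
#' @export
summarize_sample <- function(curves, n_expected = 6L, prominence = NULL) {
  if (length(curves) != n_expected) {
    stop("expected ", n_expected, " curves, got ", length(curves), call. = FALSE)
  }
  peaks <- matrix(NA_real_, length(curves), 2L)
  for (i in seq_along(curves)) {
    res <- tryCatch(extract_peak_forces(curves[[i]], prominence),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      stop("peak extraction failed for curve ", i, ": ", conditionMessage(res),
        call. = FALSE
      )
    }
    peaks[i, ] <- res
  }
  c(F1 = mean(peaks[, 1L]), F2 = mean(peaks[, 2L]))
}

#' Build a hardness table from per-sample curve sets
#'
#' @param curve_sets named list (sample id -> list of curves).
#' @param batch_day optional numeric vector of storage days, recycled row
#'   order matching `names(curve_sets)`.
#' @inheritParams summarize_sample
#' @return data frame `sample_id`, `batch_day`, `F1`, `F2`.
#' @export
hardness_from_curves <- function(curve_sets, batch_day = NA_real_,
                                 n_expected = 6L, prominence = NULL) {
  stopifnot(is.list(curve_sets), !is.null(names(curve_sets)))
  peaks <- t(vapply(
    curve_sets, summarize_sample,
    numeric(2), n_expected = n_expected, prominence = prominence
  ))
  data.frame(
    sample_id = names(curve_sets),
    batch_day = rep_len(batch_day, length(curve_sets)),
    F1 = peaks[, 1L], F2 = peaks[, 2L],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Descriptive statistics of a hardness table
#'
#' Minimum, maximum, mean, sample standard deviation (n-1 denominator) and
#' count for F1 and F2 — the schema of the study's descriptive table.
#'
#' @param hardness data frame with columns `F1` and `F2`.
#' @return data frame with one row per variable and columns `variable`,
#'   `min`, `max`, `mean`, `sd`, `n`; with a single observation `sd` is
#'   reported as 0 and the attribute `sd_undefined` is set.
#' @export
describe_hardness <- function(hardness) {
  stopifnot(is.data.frame(hardness))
  if (!nrow(hardness)) stop("empty hardness table", call. = FALSE)
  one <- function(v, x) {
    data.frame(
      variable = v, min = min(x), max = max(x), mean = mean(x),
      sd = if (length(x) > 1L) stats::sd(x) else 0,
      n = length(x), stringsAsFactors = FALSE
    )
  }
  out <- rbind(one("F1", hardness$F1), one("F2", hardness$F2))
  if (nrow(hardness) == 1L) attr(out, "sd_undefined") <- TRUE
  out
}
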