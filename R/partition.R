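#' SPXY calibration/prediction partitioning
#'
#' Sample-set partitioning based on joint X-Y distance: the Kennard-Stone
#' max-min design extended with the response, so calibration samples span
#' both spectral space and the hardness range. The joint distance is
#' `d(i,j) = dX(i,j)/max(dX) + dy(i,j)/max(dy)` with Euclidean `dX` and
#' absolute-difference `dy`. The two samples at maximum joint distance seed
#' the calibration set; each following pick is the sample whose minimum
#' distance to the already-chosen set is largest (ties: lowest index), until
#' `floor(n * calibration_fraction)` samples are chosen. Fully deterministic.
#'
#' Distances are computed on the raw spectra: partitioning precedes any
#' preprocessing in the workflow, so the split is common to all preprocessing
#' arms.
#'
#' @param X a [spectra_set()] or numeric matrix (samples in rows).
#' @param y numeric response, one value per row of `X`.
#' @param calibration_fraction fraction of samples for calibration (study
#'   design: 3:1, i.e. 0.75).
#' @return list of class `split_result`: `calibration_ids`,
#'   `prediction_ids`, `ratio`, `method`.
#' @export
spxy_split <- function(X, y, calibration_fraction = 0.75) {
  ids <- NULL
  if (inherits(X, "spectra_set")) {
    ids <- X$sample_ids
    X <- X$absorbance
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(ids)) ids <- rownames(X) %||% as.character(seq_len(n))
  if (length(y) != n) stop("y length must equal nrow(X)", call. = FALSE)
  if (n < 4L) stop("need at least 4 samples to partition", call. = FALSE)
  n_cal <- floor(n * calibration_fraction)
  if (n_cal < 2L || n_cal >= n) {
    stop("calibration_fraction leaves fewer than 2 samples on one side",
      call. = FALSE
    )
  }

  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, `-`))
  if (max(dx) == 0) stop("degenerate data: all spectra identical", call. = FALSE)
  if (max(dy) == 0) stop("degenerate data: all responses identical", call. = FALSE)
  d <- dx / max(dx) + dy / max(dy)

  sel <- logical(n)
  seedpair <- which(d == max(d), arr.ind = TRUE)[1L, ] # lowest index pair wins
  sel[seedpair] <- TRUE
  mind <- pmin(d[, seedpair[1L]], d[, seedpair[2L]])
  while (sum(sel) < n_cal) {
    mind[sel] <- -Inf
    pick <- which.max(mind) # which.max takes the first maximum: lowest index
    sel[pick] <- TRUE
    mind <- pmin(mind, d[, pick])
  }

  structure(
    list(
      calibration_ids = ids[sel],
      prediction_ids = ids[!sel],
      ratio = calibration_fraction,
      method = "SPXY"
    ),
    class = "split_result"
  )
}

#' Kennard-Stone partitioning (X-only baseline)
#'
#' Same max-min construction as [spxy_split()] but on the spectral distance
#' alone; provided as a baseline, not tuned.
#'
#' @inheritParams spxy_split
#' @return a `split_result`.
#' @export
kennard_stone_split <- function(X, calibration_fraction = 0.75) {
  ids <- NULL
  if (inherits(X, "spectra_set")) {
    ids <- X$sample_ids
    X <- X$absorbance
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(ids)) ids <- rownames(X) %||% as.character(seq_len(n))
  if (n < 4L) stop("need at least 4 samples to partition", call. = FALSE)
  n_cal <- floor(n * calibration_fraction)
  d <- as.matrix(stats::dist(X))
  if (max(d) == 0) stop("degenerate data: all spectra identical", call. = FALSE)
  sel <- logical(n)
  seedpair <- which(d == max(d), arr.ind = TRUE)[1L, ]
  sel[seedpair] <- TRUE
  mind <- pmin(d[, seedpair[1L]], d[, seedpair[2L]])
  while (sum(sel) < n_cal) {
    mind[sel] <- -Inf
    pick <- which.max(mind)
    sel[pick] <- TRUE
    mind <- pmin(mind, d[, pick])
  }
  structure(
    list(
      calibration_ids = ids[sel], prediction_ids = ids[!sel],
      ratio = calibration_fraction, method = "KS"
    ),
    class = "split_result"
  )
}

#' Random partitioning baseline
#'
#' @inheritParams spxy_split
#' @param seed integer seed.
#' @return a `split_result`.
#' @export
random_split <- function(X, calibration_fraction = 0.75, seed = 1L) {
  ids <- if (inherits(X, "spectra_set")) X$sample_ids else
    rownames(as.matrix(X)) %||% as.character(seq_len(nrow(as.matrix(X))))
  n <- length(ids)
  n_cal <- floor(n * calibration_fraction)
  cal <- with_seed(seed, sort(sample(n, n_cal)))
  structure(
    list(
      calibration_ids = ids[cal], prediction_ids = ids[-cal],
      ratio = calibration_fraction, method = "random"
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(
    "<split_result> ", x$method, ": ", length(x$calibration_ids),
    " calibration / ", length(x$prediction_ids), " prediction\n",
    sep = ""
  )
  invisible(x)
}

#' Serialize / read a split as JSON id lists
#'
#' @param split a `split_result`.
#' @param path JSON file.
#' @return `path` invisibly (write); a `split_result` (read).
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(
      method = split$method, ratio = split$ratio,
      calibration_ids = split$calibration_ids,
      prediction_ids = split$prediction_ids
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      calibration_ids = as.character(x$calibration_ids),
      prediction_ids = as.character(x$prediction_ids),
      ratio = x$ratio, method = x$method
    ),
    class = "split_result"
  )
}
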