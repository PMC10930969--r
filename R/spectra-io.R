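#' Construct a spectra set
#'
#' The central container of the package: an absorbance matrix (samples in
#' rows) with its wavenumber axis and unique sample identifiers. The
#' wavenumber axis is canonically stored strictly descending (10,000 down to
#' 4000 cm-1 in the study design); ascending input is reversed.
#'
#' @param wavenumbers numeric vector, cm-1, strictly monotone (descending
#'   canonical; ascending is reversed with a message).
#' @param absorbance numeric matrix, `n_samples x length(wavenumbers)`.
#' @param sample_ids character vector of unique sample labels.
#' @return an object of class `spectra_set` with fields `wavenumbers`,
#'   `absorbance`, `sample_ids`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(wavenumbers)) {
    stop("wavenumbers must be unique", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (all(d > 0)) {
    message("wavenumbers ascend; reversing to canonical descending order")
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  } else if (!all(d < 0)) {
    stop("wavenumbers must be strictly monotone", call. = FALSE)
  }
  if (ncol(absorbance) != length(wavenumbers)) {
    stop("absorbance column count must equal wavenumber length", call. = FALSE)
  }
  if (nrow(absorbance) != length(sample_ids)) {
    stop("one sample_id per absorbance row required", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample_id: ", sample_ids[duplicated(sample_ids)][1L],
      call. = FALSE
    )
  }
  if (anyNA(absorbance)) stop("absorbance contains NA", call. = FALSE)
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- NULL
  structure(
    list(
      wavenumbers = wavenumbers, absorbance = absorbance,
      sample_ids = sample_ids
    ),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(
    "<spectra_set> ", nrow(x$absorbance), " samples x ",
    length(x$wavenumbers), " wavenumbers (",
    max(x$wavenumbers), "-", min(x$wavenumbers), " cm-1)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set
#'
#' @param x a `spectra_set`.
#' @param i sample selector (ids, logical or integer).
#' @param j wavenumber index selector (integer positions into the axis).
#' @param ... ignored.
#' @return a `spectra_set`.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$wavenumbers)
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (anyNA(i)) stop("unknown sample id in subset", call. = FALSE)
  spectra_set(x$wavenumbers[j], x$absorbance[i, j, drop = FALSE], x$sample_ids[i])
}

#' Decimate the wavenumber axis
#'
#' Keeps every `every`-th point of the axis (first point always kept). Used to
#' trade spectral resolution for speed in simulations and model sweeps.
#'
#' @param spectra a `spectra_set`.
#' @param every positive integer stride.
#' @return a `spectra_set` on the thinned axis.
#' @export
decimate_spectra <- function(spectra, every = 4L) {
  stopifnot(inherits(spectra, "spectra_set"), every >= 1)
  keep <- seq(1L, length(spectra$wavenumbers), by = as.integer(every))
  spectra[, keep]
}

#' Write spectra to the package's CSV dialect
#'
#' Row 1 holds `sample_id` followed by the wavenumbers (descending); each
#' subsequent row is a sample id followed by its absorbances. Values are
#' written with 17 significant digits so a save/load round trip preserves
#' doubles exactly.
#'
#' @param spectra a `spectra_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  header <- paste(c("sample_id", sprintf("%.17g", spectra$wavenumbers)),
    collapse = ","
  )
  rows <- vapply(seq_along(spectra$sample_ids), function(i) {
    paste(c(
      spectra$sample_ids[i],
      sprintf("%.17g", spectra$absorbance[i, ])
    ), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Load spectra from the package's CSV dialect
#'
#' @param path CSV file (row 1: `sample_id` + numeric wavenumbers; rows 2+:
#'   id, absorbances).
#' @param expected_range optional length-2 numeric, e.g. `c(10000, 4000)`;
#'   loading fails if the axis extends outside it.
#' @return a `spectra_set`.
#' @export
load_spectra <- function(path, expected_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("spectra file needs a header and >= 1 sample row", call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  wn <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(wn)) stop("header row does not parse as numeric wavenumbers", call. = FALSE)
  p <- length(wn)
  ids <- character(length(lines) - 1L)
  mat <- matrix(NA_real_, length(lines) - 1L, p)
  for (i in seq_along(ids)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
    if (length(cells) != p + 1L) {
      stop("ragged row ", i + 1L, ": expected ", p + 1L, " cells, got ",
        length(cells),
        call. = FALSE
      )
    }
    vals <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(vals)) stop("non-numeric cell in row ", i + 1L, call. = FALSE)
    ids[i] <- cells[1L]
    mat[i, ] <- vals
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  if (!is.null(expected_range)) {
    lo <- min(expected_range)
    hi <- max(expected_range)
    if (min(wn) < lo || max(wn) > hi) {
      stop(
        "wavenumber axis [", min(wn), ", ", max(wn),
        "] outside expected range [", lo, ", ", hi, "]",
        call. = FALSE
      )
    }
  }
  spectra_set(wn, mat, ids)
}

#' Average replicate spectra per sample
#'
#' The acquisition protocol records three spectra per fruit (equatorial
#' points) and uses their mean as the sample spectrum; this implements that
#' averaging for an arbitrary replicate map.
#'
#' @param spectra a `spectra_set` whose rows are replicate scans.
#' @param replicate_map named list: output sample id -> character vector of
#'   replicate ids present in `spectra`.
#' @return a `spectra_set` with one row per entry of `replicate_map`.
#' @export
average_replicates <- function(spectra, replicate_map) {
  stopifnot(inherits(spectra, "spectra_set"), is.list(replicate_map))
  if (is.null(names(replicate_map)) || any(names(replicate_map) == "")) {
    stop("replicate_map must be a named list", call. = FALSE)
  }
  rows <- t(vapply(names(replicate_map), function(id) {
    reps <- replicate_map[[id]]
    miss <- setdiff(reps, spectra$sample_ids)
    if (length(miss)) {
      stop("missing replicate id(s) for sample ", id, ": ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    colMeans(spectra$absorbance[match(reps, spectra$sample_ids), , drop = FALSE])
  }, numeric(length(spectra$wavenumbers))))
  spectra_set(spectra$wavenumbers, rows, names(replicate_map))
}

#' Align spectra with a hardness table
#'
#' Inner join on `sample_id`, preserving the spectra row order; ids present in
#' only one input are reported as dropped.
#'
#' @param spectra a `spectra_set`.
#' @param hardness data frame with columns `sample_id`, `F1`, `F2` (and
#'   optionally `batch_day`).
#' @return list with `spectra` (subset, original order), `hardness` (reordered
#'   to match) and `dropped` (character vector of unmatched ids).
#' @export
align_spectra_hardness <- function(spectra, hardness) {
  stopifnot(inherits(spectra, "spectra_set"), is.data.frame(hardness))
  common <- intersect(spectra$sample_ids, hardness$sample_id)
  if (!length(common)) stop("no sample ids in common", call. = FALSE)
  keep <- spectra$sample_ids[spectra$sample_ids %in% common]
  dropped <- c(
    setdiff(spectra$sample_ids, common),
    setdiff(hardness$sample_id, common)
  )
  h <- hardness[match(keep, hardness$sample_id), , drop = FALSE]
  rownames(h) <- NULL
  list(spectra = spectra[keep, ], hardness = h, dropped = dropped)
}

#' Write / load the hardness CSV dialect
#'
#' Columns: `sample_id, batch_day, F1_gN, F2_gN`.
#'
#' @param hardness data frame with `sample_id`, `batch_day`, `F1`, `F2`.
#' @param path CSV file.
#' @return `path` invisibly (write); a data frame with columns `sample_id`,
#'   `batch_day`, `F1`, `F2` (load).
#' @export
write_hardness <- function(hardness, path) {
  stopifnot(all(c("sample_id", "batch_day", "F1", "F2") %in% names(hardness)))
  out <- data.frame(
    sample_id = hardness$sample_id,
    batch_day = hardness$batch_day,
    F1_gN = sprintf("%.17g", hardness$F1),
    F2_gN = sprintf("%.17g", hardness$F2)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hardness
#' @export
load_hardness <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "batch_day", "F1_gN", "F2_gN")
  if (!all(need %in% names(raw))) {
    stop("hardness CSV must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  data.frame(
    sample_id = as.character(raw$sample_id),
    batch_day = as.numeric(raw$batch_day),
    F1 = as.numeric(raw$F1_gN),
    F2 = as.numeric(raw$F2_gN),
    stringsAsFactors = FALSE
  )
}
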