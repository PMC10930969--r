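#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`: the fraction of response variance explained
#' by the predictions, used for both calibration (`R2_C`) and prediction
#' (`R2_P`) sets.
#'
#' @param y_obs observed responses (non-constant).
#' @param y_pred predicted responses, same length.
#' @return unitless scalar `<= 1`.
#' @export
r_squared <- function(y_obs, y_pred) {
  if (!length(y_obs) || length(y_obs) != length(y_pred)) {
    stop("y_obs and y_pred must be equal-length, nonempty", call. = FALSE)
  }
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  if (ss_tot == 0) stop("undefined variance: y_obs is constant", call. = FALSE)
  1 - sum((y_obs - y_pred)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in the response units (gN).
#' @export
rmse <- function(y_obs, y_pred) {
  if (!length(y_obs) || length(y_obs) != length(y_pred)) {
    stop("y_obs and y_pred must be equal-length, nonempty", call. = FALSE)
  }
  sqrt(mean((y_obs - y_pred)^2))
}

#' Residual predictive deviation
#'
#' `RPD = SD / RMSE_P`, where SD is the sample standard deviation (n-1) of
#' the prediction-set observations. The qualitative band follows the
#' conventional reading: below 2 the model is insufficient for
#' quantitation, in `[2, 2.5)` it supports approximate quantitative
#' assessment, and at 2.5 or above it has strong predictive ability (the
#' 2.5 boundary is closed on the "strong" side).
#'
#' @param y_obs_prediction_set observed prediction-set responses (length
#'   >= 2).
#' @param rmse_p prediction-set RMSE (`> 0`; a zero RMSE would imply an
#'   infinite RPD and is rejected explicitly).
#' @return list with `rpd` (unitless) and `band` (`"insufficient"`,
#'   `"approximate"`, `"strong"`).
#' @export
rpd <- function(y_obs_prediction_set, rmse_p) {
  if (length(y_obs_prediction_set) < 2L) {
    stop("prediction set must have >= 2 observations", call. = FALSE)
  }
  if (rmse_p <= 0) {
    stop("rmse_p must be > 0 (zero would make RPD infinite)", call. = FALSE)
  }
  value <- stats::sd(y_obs_prediction_set) / rmse_p
  band <- if (value >= 2.5) "strong" else if (value >= 2) "approximate" else "insufficient"
  list(rpd = value, band = band)
}

#' Assemble one model-evaluation row
#'
#' Computes `R2_C`, `RMSE_C` on the calibration set and `R2_P`, `RMSE_P`,
#' `RPD` on the prediction set — the row type of the study's comparison
#' tables.
#'
#' @param response `"F1"` or `"F2"`.
#' @param model,preprocessing,selection character labels of the pipeline arm.
#' @param y_cal,yhat_cal observed/predicted calibration responses.
#' @param y_pred,yhat_pred observed/predicted prediction-set responses.
#' @return one-row data frame (an `eval_report`).
#' @export
eval_report <- function(response, model, preprocessing, selection,
                        y_cal, yhat_cal, y_pred, yhat_pred) {
  rmse_p <- rmse(y_pred, yhat_pred)
  rp <- rpd(y_pred, rmse_p)
  data.frame(
    response = response, model = model, preprocessing = preprocessing,
    selection = selection,
    R2_C = r_squared(y_cal, yhat_cal),
    RMSE_C = rmse(y_cal, yhat_cal),
    R2_P = r_squared(y_pred, yhat_pred),
    RMSE_P = rmse_p,
    RPD = rp$rpd,
    RPD_band = rp$band,
    stringsAsFactors = FALSE
  )
}

#' Rank evaluation reports into a comparison table
#'
#' Binds the reports, checks that each `(response, model, preprocessing,
#' selection)` key appears once, sorts by prediction-set R2 descending and
#' flags the best row per response.
#'
#' @param reports list of [eval_report()] rows, or a data frame of them.
#' @return data frame with an added logical column `best`.
#' @export
build_comparison <- function(reports) {
  tab <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
  if (!nrow(tab)) stop("no reports to compare", call. = FALSE)
  key <- with(tab, paste(response, model, preprocessing, selection, sep = "|"))
  if (anyDuplicated(key)) {
    stop("duplicate report key: ", key[duplicated(key)][1L], call. = FALSE)
  }
  tab <- tab[order(-tab$R2_P), , drop = FALSE]
  tab$best <- FALSE
  for (r in unique(tab$response)) {
    rows <- which(tab$response == r)
    tab$best[rows[1L]] <- TRUE # already sorted by R2_P
  }
  rownames(tab) <- NULL
  tab
}
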