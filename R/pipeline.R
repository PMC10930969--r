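#' Configure a full hardness-calibration experiment
#'
#' One configuration drives the whole workflow: simulate (or load) spectra
#' and hardness, SPXY-split per response, preprocess
#' (fit-on-calibration/apply-to-both), select wavelengths on the calibration
#' set, fit the regression models, and assemble the ranked comparison table.
#' The cross-product of `preprocessing x selection x models x responses` is
#' executed; `"none"` preprocessing and `"full"` (all wavelengths) selection
#' are explicit baseline levels, so preprocessing-only and selection-only
#' comparisons are expressible.
#'
#' @param synthetic a [synthetic_config()] used when no CSV paths are given.
#' @param spectra_csv,hardness_csv optional paths to real data in the
#'   package CSV dialects; both must be given to override simulation.
#' @param calibration_fraction SPXY calibration fraction (study design 3:1,
#'   i.e. 0.75).
#' @param preprocessing subset of `c("none", "MA", "MC")`.
#' @param selection subset of `c("full", "CARS", "SPA", "UVE")`.
#' @param models subset of `c("grids_rf", "ga_svr")`.
#' @param responses subset of `c("F1", "F2")`.
#' @param ma_window moving-average half-width.
#' @param decimate keep every `decimate`-th wavenumber (1 = full axis).
#' @param seed master seed; every stage derives its own stream.
#' @param output_dir if non-`NULL`, artifacts (hardness CSV, split and
#'   selection JSONs, comparison CSV) are written there.
#' @param cars,spa,uve,rf,ga named lists of extra arguments forwarded to
#'   [cars_select()], [spa_select()], [uve_select()], [rf_grid_config()] and
#'   [ga_config()] — the knobs used to scale problem sizes.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       spectra_csv = NULL, hardness_csv = NULL,
                       calibration_fraction = 0.75,
                       preprocessing = c("none", "MA", "MC"),
                       selection = c("full", "CARS", "SPA", "UVE"),
                       models = c("grids_rf", "ga_svr"),
                       responses = c("F1", "F2"),
                       ma_window = 3L, decimate = 4L, seed = 42L,
                       output_dir = NULL,
                       cars = list(), spa = list(), uve = list(),
                       rf = list(), ga = list()) {
  preprocessing <- match.arg(preprocessing, c("none", "MA", "MC"), several.ok = TRUE)
  selection <- match.arg(selection, c("full", "CARS", "SPA", "UVE"), several.ok = TRUE)
  models <- match.arg(models, c("grids_rf", "ga_svr"), several.ok = TRUE)
  responses <- match.arg(responses, c("F1", "F2"), several.ok = TRUE)
  stopifnot(
    length(preprocessing) >= 1L, length(selection) >= 1L,
    length(models) >= 1L, length(responses) >= 1L
  )
  structure(
    list(
      synthetic = synthetic, spectra_csv = spectra_csv,
      hardness_csv = hardness_csv,
      calibration_fraction = calibration_fraction,
      preprocessing = preprocessing, selection = selection,
      models = models, responses = responses,
      ma_window = as.integer(ma_window), decimate = as.integer(decimate),
      seed = as.integer(seed), output_dir = output_dir,
      cars = cars, spa = spa, uve = uve, rf = rf, ga = ga
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `synthetic`
#' block holds [synthetic_config()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  do.call(run_config, raw)
}

run_selection <- function(method, X, y, wn, seed, config) {
  switch(method,
    full = selection_result("full", seq_len(ncol(X)), wn),
    CARS = do.call(cars_select, c(
      list(X = X, y = y, wavenumbers = wn, seed = seed), config$cars
    )),
    SPA = do.call(spa_select, c(
      list(X = X, y = y, wavenumbers = wn), config$spa
    )),
    UVE = do.call(uve_select, c(
      list(X = X, y = y, wavenumbers = wn, seed = seed), config$uve
    ))
  )
}

run_model <- function(model, X, y, seed, config) {
  switch(model,
    grids_rf = grids_rf_fit(
      X, y,
      do.call(rf_grid_config, c(list(seed = seed), config$rf))
    ),
    ga_svr = ga_svr_fit(
      X, y,
      do.call(ga_config, c(list(seed = seed), config$ga))
    )
  )
}

#' Run the full calibration experiment
#'
#' Executes every combination of the configured pipeline arms. A failure in
#' one combination is logged and skipped; the remaining combinations still
#' run. Re-running with the same configuration reproduces every number
#' exactly.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return list of class `experiment_result`: `comparison` (ranked table),
#'   `reports`, `splits` (per response), `selections` (per
#'   response/preprocessing/method), `failures` (character log of skipped
#'   combinations), `data` (the `synthetic_dataset` or loaded data).
#' @export
run_experiment <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(config$spectra_csv) && !is.null(config$hardness_csv)) {
    spectra <- load_spectra(config$spectra_csv)
    hardness <- load_hardness(config$hardness_csv)
    joined <- align_spectra_hardness(spectra, hardness)
    spectra <- joined$spectra
    hardness <- joined$hardness
    data <- list(spectra = spectra, hardness = hardness)
  } else {
    data <- generate_spectra(config$synthetic, curves = FALSE)
    spectra <- data$spectra
    hardness <- data$hardness
  }
  if (config$decimate > 1L) spectra <- decimate_spectra(spectra, config$decimate)
  wn <- spectra$wavenumbers
  say("data: %d samples x %d wavenumbers", nrow(spectra$absorbance), length(wn))

  reports <- list()
  splits <- list()
  selections <- list()
  failures <- character(0)

  for (resp in config$responses) {
    y_all <- hardness[[resp]]
    names(y_all) <- hardness$sample_id
    split <- spxy_split(spectra, y_all, config$calibration_fraction)
    splits[[resp]] <- split
    cal_ids <- split$calibration_ids
    pred_ids <- split$prediction_ids
    say(
      "%s: SPXY split %d calibration / %d prediction", resp,
      length(cal_ids), length(pred_ids)
    )

    for (prep in config$preprocessing) {
      state <- preprocess_fit(prep, spectra[cal_ids, ], w = config$ma_window)
      Xcal_s <- preprocess_apply(state, spectra[cal_ids, ])
      Xpred_s <- preprocess_apply(state, spectra[pred_ids, ])
      Xcal <- Xcal_s$absorbance
      Xpred <- Xpred_s$absorbance
      y_cal <- y_all[cal_ids]
      y_pred <- y_all[pred_ids]

      for (selm in config$selection) {
        tag <- paste(resp, prep, selm, sep = "/")
        sel <- tryCatch(
          run_selection(
            selm, Xcal, y_cal, wn,
            derive_seed(config$seed, paste0("select/", tag)), config
          ),
          error = function(e) e
        )
        if (inherits(sel, "error")) {
          failures <- c(failures, sprintf("%s: selection failed: %s", tag, conditionMessage(sel)))
          next
        }
        if (!length(sel$selected)) {
          failures <- c(failures, sprintf("%s: selection empty", tag))
          next
        }
        selections[[tag]] <- sel
        say("%s: %d wavelengths", tag, length(sel$selected))

        for (mod in config$models) {
          mtag <- paste(tag, mod, sep = "/")
          rep_row <- tryCatch(
            {
              fit <- run_model(
                mod, Xcal[, sel$selected, drop = FALSE], y_cal,
                derive_seed(config$seed, paste0("fit/", mtag)), config
              )
              eval_report(
                resp, mod, prep, selm,
                y_cal, predict(fit, Xcal[, sel$selected, drop = FALSE]),
                y_pred, predict(fit, Xpred[, sel$selected, drop = FALSE])
              )
            },
            error = function(e) e
          )
          if (inherits(rep_row, "error")) {
            failures <- c(failures, sprintf("%s: model failed: %s", mtag, conditionMessage(rep_row)))
            next
          }
          reports[[mtag]] <- rep_row
          say(
            "%s: R2_P %.3f RMSE_P %.3f", mtag,
            rep_row$R2_P, rep_row$RMSE_P
          )
        }
      }
    }
  }

  comparison <- if (length(reports)) build_comparison(reports) else NULL

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_hardness(hardness, file.path(config$output_dir, "hardness.csv"))
    for (resp in names(splits)) {
      write_split(splits[[resp]], file.path(config$output_dir, sprintf("split_%s.json", resp)))
    }
    for (tag in names(selections)) {
      write_selection(
        selections[[tag]],
        file.path(config$output_dir, paste0("selection_", gsub("/", "_", tag), ".json"))
      )
    }
    if (!is.null(comparison)) {
      utils::write.csv(comparison,
        file.path(config$output_dir, "comparison.csv"),
        row.names = FALSE
      )
    }
  }

  structure(
    list(
      comparison = comparison, reports = reports, splits = splits,
      selections = selections, failures = failures, data = data,
      config = config
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", length(x$reports), " model evaluations, ",
    length(x$failures), " failures\n",
    sep = ""
  )
  if (!is.null(x$comparison)) {
    print(utils::head(x$comparison[, c(
      "response", "model", "preprocessing",
      "selection", "R2_P", "RMSE_P", "RPD", "best"
    )], 10))
  }
  invisible(x)
}
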