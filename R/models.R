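#' Grid configuration for the grid-searched random forest
#'
#' @param ntree_grid tree counts to scan (default 100, 200, ..., 1000).
#' @param mtry_grid candidate per-node feature counts; `NULL` derives 5
#'   log-spaced values between `ceiling(p/10)` and `p` from the data at fit
#'   time.
#' @param k_folds cross-validation folds (default 5).
#' @param seed integer seed controlling fold assignment and per-fit forests.
#' @return list of class `rf_grid_config`.
#' @export
rf_grid_config <- function(ntree_grid = seq(100L, 1000L, by = 100L),
                           mtry_grid = NULL, k_folds = 5L, seed = 1L) {
  stopifnot(length(ntree_grid) >= 1L, all(ntree_grid >= 1), k_folds >= 2L)
  structure(
    list(
      ntree_grid = sort(unique(as.integer(ntree_grid))),
      mtry_grid = if (!is.null(mtry_grid)) sort(unique(as.integer(mtry_grid))),
      k_folds = as.integer(k_folds), seed = as.integer(seed)
    ),
    class = "rf_grid_config"
  )
}

default_mtry_grid <- function(p) {
  lo <- max(1L, ceiling(p / 10))
  as.integer(sort(unique(pmin(p, pmax(1L, round(exp(
    seq(log(lo), log(p), length.out = 5)
  )))))))
}

#' Random forest regression tuned by exhaustive grid search
#'
#' Evaluates every `(ntree, mtry)` pair of the grid by k-fold
#' cross-validation (fold assignment fixed once by the seed and shared by
#' all pairs, so comparisons are paired), pools the held-out squared errors
#' into one CV MSE per pair, and retrains on the full calibration set at the
#' argmin. Ties break to the smaller `ntree`, then the smaller `mtry`. Each
#' forest is grown under a seed derived from `(seed, ntree, mtry, fold)`, so
#' an independent re-evaluation of any grid point reproduces its CV error
#' exactly.
#'
#' @param X calibration predictor matrix (samples in rows).
#' @param y calibration response.
#' @param config an [rf_grid_config()].
#' @return object of class `fitted_model` with fields `kind = "grids_rf"`,
#'   `best_hyperparameters` (`ntree`, `mtry`), `cv_error` (MSE),
#'   `cv_table`, `model`, `n_features`, `folds`.
#' @export
grids_rf_fit <- function(X, y, config = rf_grid_config()) {
  stopifnot(inherits(config, "rf_grid_config"))
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("y length must equal nrow(X)", call. = FALSE)
  mtry_grid <- config$mtry_grid %||% default_mtry_grid(p)
  if (any(mtry_grid > p)) {
    stop("parameter error: mtry values ", paste(mtry_grid[mtry_grid > p], collapse = ", "),
      " exceed n_features = ", p,
      call. = FALSE
    )
  }
  folds <- seeded_folds(n, config$k_folds, derive_seed(config$seed, "rf-folds"))

  grid <- expand.grid(
    mtry = as.integer(mtry_grid),
    ntree = as.integer(config$ntree_grid)
  )[, c("ntree", "mtry")]
  grid <- grid[order(grid$ntree, grid$mtry), ]
  rownames(grid) <- NULL
  cv_mse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sq <- numeric(n)
    for (f in seq_len(config$k_folds)) {
      hold <- folds == f
      fit <- with_seed(
        derive_seed(config$seed, sprintf("rf/%d/%d/%d", grid$ntree[g], grid$mtry[g], f)),
        randomForest::randomForest(
          x = X[!hold, , drop = FALSE], y = y[!hold],
          ntree = grid$ntree[g], mtry = grid$mtry[g]
        )
      )
      sq[hold] <- (y[hold] - predict(fit, X[hold, , drop = FALSE]))^2
    }
    cv_mse[g] <- mean(sq)
  }
  best <- which.min(cv_mse) # first minimum: smallest ntree then mtry
  final <- with_seed(
    derive_seed(config$seed, "rf-final"),
    randomForest::randomForest(
      x = X, y = y,
      ntree = grid$ntree[best], mtry = grid$mtry[best]
    )
  )
  structure(
    list(
      kind = "grids_rf",
      best_hyperparameters = list(ntree = grid$ntree[best], mtry = grid$mtry[best]),
      cv_error = cv_mse[best],
      cv_table = cbind(grid, cv_mse = cv_mse),
      model = final,
      n_features = p,
      folds = folds
    ),
    class = "fitted_model"
  )
}

#' Gaussian radial basis kernel
#'
#' `K(x_i, x_j) = exp(-gamma * ||x_i - x_j||^2)`, the SVR kernel of the
#' workflow.
#'
#' @param x_i,x_j equal-length numeric vectors.
#' @param gamma non-negative kernel width parameter.
#' @return kernel similarity in `(0, 1]`.
#' @export
rbf_kernel <- function(x_i, x_j, gamma) {
  if (length(x_i) != length(x_j)) stop("vector length mismatch", call. = FALSE)
  stopifnot(gamma >= 0)
  exp(-gamma * sum((x_i - x_j)^2))
}

#' Configuration of the GA-tuned support vector regression
#'
#' The genetic algorithm evolves `(c, gamma)` pairs encoded on the log10
#' scale within the given ranges. A "generation" is one evaluated
#' population: generation 1 is the random initial population, so with
#' `n_generations = 1` the fit is an exhaustive argmin over the initial
#' individuals. Fitness is the k-fold cross-validated MSE of an RBF-kernel
#' epsilon-SVR (minimised; the best individual is carried over unchanged —
#' elitism — so the best fitness trajectory is non-increasing). Evolution
#' stops early when the best fitness has not improved by more than `tol`
#' for `patience` generations.
#'
#' @param population_size individuals per generation (>= 4, default 20).
#' @param n_generations populations evaluated (default 50).
#' @param crossover_rate probability a child is a random blend of its two
#'   parents (default 0.7).
#' @param mutation_rate per-gene probability of a Gaussian log-scale
#'   perturbation (default 0.05).
#' @param c_range,gamma_range positive search intervals for the SVR cost and
#'   kernel width (defaults `[1e-2, 1e2]`).
#' @param k_folds CV folds (default 5).
#' @param epsilon SVR epsilon-insensitive tube width (default 0.01).
#' @param patience,tol early-stopping window and improvement threshold.
#' @param seed integer seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L, n_generations = 50L,
                      crossover_rate = 0.7, mutation_rate = 0.05,
                      c_range = c(1e-2, 1e2), gamma_range = c(1e-2, 1e2),
                      k_folds = 5L, epsilon = 0.01, patience = 10L,
                      tol = 1e-6, seed = 1L) {
  stopifnot(
    population_size >= 4L, n_generations >= 1L,
    crossover_rate >= 0, crossover_rate <= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    all(c_range > 0), all(gamma_range > 0),
    diff(c_range) > 0, diff(gamma_range) > 0, k_folds >= 2L
  )
  structure(
    list(
      population_size = as.integer(population_size),
      n_generations = as.integer(n_generations),
      crossover_rate = crossover_rate, mutation_rate = mutation_rate,
      c_range = c_range, gamma_range = gamma_range,
      k_folds = as.integer(k_folds), epsilon = epsilon,
      patience = as.integer(patience), tol = tol, seed = as.integer(seed)
    ),
    class = "ga_config"
  )
}

svr_fit <- function(X, y, cost, gamma, epsilon) {
  e1071::svm(
    x = X, y = y, type = "eps-regression", kernel = "radial",
    cost = cost, gamma = gamma, epsilon = epsilon, scale = FALSE
  )
}

svr_cv_mse <- function(X, y, cost, gamma, epsilon, folds) {
  sq <- numeric(length(y))
  for (f in unique(folds)) {
    hold <- folds == f
    fit <- svr_fit(X[!hold, , drop = FALSE], y[!hold], cost, gamma, epsilon)
    sq[hold] <- (y[hold] - predict(fit, X[hold, , drop = FALSE]))^2
  }
  mean(sq)
}

#' Support vector regression tuned by a genetic algorithm
#'
#' See [ga_config()] for the evolutionary scheme. Returns the SVR retrained
#' on the full calibration set at the best `(c, gamma)` found.
#'
#' @inheritParams grids_rf_fit
#' @param config a [ga_config()].
#' @return object of class `fitted_model` with fields `kind = "ga_svr"`,
#'   `best_hyperparameters` (`cost`, `gamma`), `cv_error` (MSE),
#'   `history` (best CV MSE per generation), `model`, `n_features`.
#' @export
ga_svr_fit <- function(X, y, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y length must equal nrow(X)", call. = FALSE)
  if (stats::sd(y) == 0) stop("degenerate response: y is constant", call. = FALSE)
  folds <- seeded_folds(n, config$k_folds, derive_seed(config$seed, "ga-folds"))
  lo <- log10(c(config$c_range[1], config$gamma_range[1]))
  hi <- log10(c(config$c_range[2], config$gamma_range[2]))
  pop_n <- config$population_size

  evaluate <- function(pop) {
    apply(pop, 1L, function(g) {
      svr_cv_mse(X, y, 10^g[1], 10^g[2], config$epsilon, folds)
    })
  }

  history <- numeric(0)
  with_seed(derive_seed(config$seed, "ga"), {
    pop <- cbind(
      stats::runif(pop_n, lo[1], hi[1]),
      stats::runif(pop_n, lo[2], hi[2])
    )
    init_pop <- pop
    mse <- evaluate(pop)
    best_gene <- pop[which.min(mse), ]
    best_mse <- min(mse)
    history <- best_mse
    stall <- 0L
    gen <- 1L
    while (gen < config$n_generations && stall < config$patience) {
      gen <- gen + 1L
      # rank selection: lower MSE -> linearly higher parenthood probability
      rk <- rank(mse, ties.method = "first")
      pr <- (pop_n - rk + 1)
      pr <- pr / sum(pr)
      newpop <- matrix(NA_real_, pop_n, 2L)
      newpop[1L, ] <- best_gene # elitism
      for (i in 2:pop_n) {
        par <- pop[sample.int(pop_n, 2L, prob = pr), , drop = FALSE]
        child <- if (stats::runif(1) < config$crossover_rate) {
          a <- stats::runif(2L)
          a * par[1L, ] + (1 - a) * par[2L, ]
        } else {
          par[1L, ]
        }
        mut <- stats::runif(2L) < config$mutation_rate
        if (any(mut)) {
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), sd = 0.1 * (hi - lo)[mut])
        }
        newpop[i, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- newpop
      mse <- evaluate(pop)
      if (min(mse) < best_mse - config$tol) {
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (min(mse) < best_mse) {
        best_mse <- min(mse)
        best_gene <- pop[which.min(mse), ]
      }
      history <- c(history, best_mse)
    }
  })

  final <- svr_fit(X, y, 10^best_gene[1], 10^best_gene[2], config$epsilon)
  structure(
    list(
      kind = "ga_svr",
      best_hyperparameters = list(cost = 10^best_gene[1], gamma = 10^best_gene[2]),
      cv_error = best_mse,
      history = history,
      model = final,
      n_features = ncol(X),
      folds = folds,
      initial_population = init_pop # log10 scale, for auditability
    ),
    class = "fitted_model"
  )
}

#' Predict hardness from a fitted model
#'
#' @param object a `fitted_model` from [grids_rf_fit()] or [ga_svr_fit()].
#' @param newdata numeric matrix whose columns match the wavelengths the
#'   model was trained on.
#' @param ... ignored.
#' @return numeric vector of predicted hardness (gN), one per row.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
      object$n_features,
      call. = FALSE
    )
  }
  unname(predict(object$model, newdata))
}

#' @export
print.fitted_model <- function(x, ...) {
  hp <- paste(names(x$best_hyperparameters),
    vapply(x$best_hyperparameters, function(v) format(v, digits = 4), ""),
    sep = "=", collapse = ", "
  )
  cat("<fitted_model> ", x$kind, " (", hp, "), CV MSE ",
    format(x$cv_error, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}
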