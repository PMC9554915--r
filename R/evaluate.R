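# Model evaluation: metrics, nested hyperparameter search, repeated
# hold-out evaluation, radius-grid scanning and pairwise model comparison.

#' Regression performance metrics
#'
#' MAE = mean absolute error, RMSE = root mean squared error, R2 =
#' coefficient of determination \eqn{1 - SS_{res}/SS_{tot}}, SC = Spearman
#' rank correlation. Units of MAE/RMSE follow the label units (mV).
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2).
#' @return Named numeric vector `c(MAE, RMSE, R2, SC)`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  if (stats::sd(y_true) == 0)
    stop("R2 undefined: y_true is constant", call. = FALSE)
  d <- y_true - y_pred
  c(MAE = mean(abs(d)),
    RMSE = sqrt(mean(d^2)),
    R2 = 1 - sum(d^2) / sum((y_true - mean(y_true))^2),
    SC = stats::cor(y_true, y_pred, method = "spearman"))
}

#' Inner grid search by k-fold cross-validation
#'
#' Exhaustively evaluates every row of the estimator's hyperparameter grid
#' by k-fold cross-validated mean MAE, with the full preprocessing fitted
#' inside each training fold. Ties are broken by grid order.
#'
#' @param X,y Training features and labels.
#' @param spec An [estimator_spec()].
#' @param k Number of folds (study value 5).
#' @param seed Integer seed controlling fold assignment and stochastic
#'   fits.
#' @return List with `params` (best row of the grid), `cv_mae` (its mean
#'   CV MAE) and `grid_mae` (mean CV MAE of every candidate).
#' @export
inner_grid_search <- function(X, y, spec, k = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  grid <- spec$grid
  stopifnot(nrow(grid) >= 1L, n >= k)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  grid_mae <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fold_mae <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (sum(tr) < 2L || sum(!tr) < 1L)
        stop("degenerate fold in grid search", call. = FALSE)
      set.seed(seed + 1009L * g + f)
      fit <- fit_pipeline(X[tr, , drop = FALSE], y[tr], spec, grid[g, ])
      pred <- predict(fit, X[!tr, , drop = FALSE])
      fold_mae[f] <- mean(abs(y[!tr] - pred))
    }
    grid_mae[g] <- mean(fold_mae)
  }
  best <- which.min(grid_mae)
  list(params = grid[best, , drop = FALSE], cv_mae = grid_mae[best],
       grid_mae = grid_mae)
}

#' Repeated hold-out evaluation of one estimator
#'
#' Per repetition: a random 80/20 train/test split, inner 5-fold grid
#' search on the training part, refit with the chosen hyperparameters on
#' the full training part, and the four metrics on the held-out part.
#' Defaults mirror the study protocol (10 repetitions, 20\% test).
#'
#' @param matrix A [build_design_matrix()] result (246 features + `E_m`),
#'   or any data frame whose last-label column is named `E_m`.
#' @param spec An [estimator_spec()].
#' @param n_repeats Number of repetitions.
#' @param test_fraction Held-out fraction per repetition.
#' @param k Inner CV folds.
#' @param seed Master seed; fully determines splits, folds and fits.
#' @return Object of class `ExperimentResult`: per-repetition `metrics`
#'   data frame (MAE, RMSE, R2, SC), chosen `params` per repetition,
#'   estimator name, radii and seeds.
#' @export
repeated_evaluation <- function(matrix, spec, n_repeats = 10,
                                test_fraction = 0.2, k = 5, seed = 1) {
  stopifnot("E_m" %in% colnames(matrix))
  y <- matrix[["E_m"]]
  X <- as.matrix(matrix[, setdiff(colnames(matrix), "E_m"), drop = FALSE])
  n <- nrow(X)
  n_test <- max(1L, round(test_fraction * n))
  metrics <- vector("list", n_repeats)
  chosen <- vector("list", n_repeats)
  rep_seeds <- seed + 7919L * seq_len(n_repeats)
  for (r in seq_len(n_repeats)) {
    rs <- rep_seeds[r]
    set.seed(rs)
    test <- sample(n, n_test)
    tr <- setdiff(seq_len(n), test)
    gs <- inner_grid_search(X[tr, , drop = FALSE], y[tr], spec, k = k,
                            seed = rs + 1L)
    set.seed(rs + 2L)
    fit <- fit_pipeline(X[tr, , drop = FALSE], y[tr], spec, gs$params)
    pred <- predict(fit, X[test, , drop = FALSE])
    metrics[[r]] <- compute_metrics(y[test], pred)
    chosen[[r]] <- gs$params
  }
  structure(list(estimator = spec$name,
                 r1 = attr(matrix, "r1"), r2 = attr(matrix, "r2"),
                 metrics = as.data.frame(do.call(rbind, metrics)),
                 params = chosen, seed = seed, rep_seeds = rep_seeds),
            class = "ExperimentResult")
}

#' @export
summary.ExperimentResult <- function(object, ...) {
  m <- object$metrics
  data.frame(estimator = object$estimator,
             r1 = if (is.null(object$r1)) NA else object$r1,
             r2 = if (is.null(object$r2)) NA else object$r2,
             metric = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             row.names = NULL)
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat("ExperimentResult:", x$estimator,
      sprintf("(r1 = %s, r2 = %s), %d repetitions\n",
              format(x$r1), format(x$r2), nrow(x$metrics)))
  s <- summary(x)
  cat(sprintf("  %-5s %8.2f +/- %.2f\n", s$metric, s$mean, s$sd), sep = "")
  invisible(x)
}

#' Scan estimator performance over the (r1, r2) radius grid
#'
#' Builds the design matrix and runs [repeated_evaluation()] at every grid
#' configuration, reporting the mean MAE surface and its argmin.
#'
#' @param records Record table for [build_design_matrix()].
#' @param spec An [estimator_spec()].
#' @param grid Data frame of (r1, r2) rows; defaults to [radius_grid()].
#' @param n_repeats,test_fraction,k,seed Passed to [repeated_evaluation()].
#' @param ... Passed to [build_design_matrix()].
#' @return List with `table` (r1, r2, mean/sd MAE per configuration),
#'   `best` (argmin row) and `results` (the `ExperimentResult` objects).
#' @export
radius_scan <- function(records, spec, grid = radius_grid(), n_repeats = 10,
                        test_fraction = 0.2, k = 5, seed = 1, ...) {
  stopifnot(nrow(grid) >= 1L)
  results <- vector("list", nrow(grid))
  mae <- sdv <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    dm <- build_design_matrix(records, r1 = grid$r1[i], r2 = grid$r2[i], ...)
    results[[i]] <- repeated_evaluation(dm, spec, n_repeats = n_repeats,
                                        test_fraction = test_fraction,
                                        k = k, seed = seed)
    mae[i] <- mean(results[[i]]$metrics$MAE)
    sdv[i] <- stats::sd(results[[i]]$metrics$MAE)
  }
  tab <- data.frame(r1 = grid$r1, r2 = grid$r2, mean_MAE = mae, sd_MAE = sdv)
  list(table = tab, best = tab[which.min(tab$mean_MAE), ],
       results = results)
}

#' Pairwise Mann–Whitney comparison of estimators
#'
#' Two-sided Mann–Whitney U rank test (normal approximation with tie
#' correction, no continuity correction) on the per-repetition metric
#' samples of every estimator pair. Identical constant samples are
#' assigned p = 1 by convention.
#'
#' @param results List of `ExperimentResult` objects with equal repetition
#'   counts.
#' @param metric One of `"MAE"`, `"RMSE"`, `"R2"`, `"SC"`.
#' @param alpha Significance level for the flags (study value 0.05).
#' @return Object of class `ComparisonReport`: `p_values` matrix,
#'   `significant` logical matrix, `metric`.
#' @export
pairwise_model_comparison <- function(results, metric = "MAE",
                                      alpha = 0.05) {
  stopifnot(length(results) >= 2L)
  nrep <- vapply(results, function(r) nrow(r$metrics), integer(1))
  stopifnot(length(unique(nrep)) == 1L)
  nm <- vapply(results, function(r) r$estimator, character(1))
  samples <- lapply(results, function(r) r$metrics[[metric]])
  p <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j) next
    xi <- samples[[i]]; xj <- samples[[j]]
    if (length(unique(c(xi, xj))) == 1L) {
      p[i, j] <- 1
    } else {
      p[i, j] <- stats::wilcox.test(xi, xj, exact = FALSE,
                                    correct = FALSE)$p.value
    }
  }
  structure(list(p_values = p, significant = p < alpha, metric = metric,
                 alpha = alpha),
            class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("Pairwise Mann-Whitney U on", x$metric,
      sprintf("(two-sided, alpha = %g)\n", x$alpha))
  print(round(x$p_values, 4))
  invisible(x)
}
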