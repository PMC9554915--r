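test_that("metrics follow their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(compute_metrics(y, y),
               c(MAE = 0, RMSE = 0, R2 = 1, SC = 1))
  off <- compute_metrics(y, y + 10)
  expect_equal(off[["MAE"]], 10)
  expect_equal(off[["RMSE"]], 10)
  expect_equal(off[["SC"]], 1)
  expect_error(compute_metrics(c(5, 5, 5), c(1, 2, 3)), "constant")

  for (s in 1:30) {
    set.seed(200 + s)
    yt <- rnorm(100, -223, 109)
    yp <- yt + rnorm(100, 0, 40)
    m <- compute_metrics(yt, yp)
    expect_equal(m, oracle_metrics(yt, yp), tolerance = 1e-12)
    expect_gte(m[["RMSE"]], m[["MAE"]])
    expect_lte(m[["R2"]], 1)
    expect_true(abs(m[["SC"]]) <= 1)
  }
})

test_that("grid search is an argmin over CV MAE with deterministic seeding", {
  pd <- generate_planted_dataset(n = 60, n_support = 2, seed = 101,
                                 feature_names = paste0("f", 1:30),
                                 n_duplicates = 0)
  X <- as.matrix(pd$matrix[, setdiff(names(pd$matrix), "E_m")])
  y <- pd$matrix$E_m
  one <- estimator_spec("LR", grid = data.frame(en_alpha = 10, en_rho = 1))
  gs1 <- suppressWarnings(inner_grid_search(X, y, one, seed = 4))
  expect_equal(gs1$params$en_alpha, 10)
  spec <- estimator_spec("LR", grid = expand.grid(en_alpha = c(10, 100),
                                                  en_rho = c(0.5, 1)))
  gs <- suppressWarnings(inner_grid_search(X, y, spec, seed = 4))
  expect_true(all(gs$cv_mae <= gs$grid_mae + 1e-12))
  gs_again <- suppressWarnings(inner_grid_search(X, y, spec, seed = 4))
  expect_identical(gs$grid_mae, gs_again$grid_mae)
  expect_identical(gs$params, gs_again$params)
})

test_that("repeated evaluation reaches the Gaussian noise floor for LR", {
  pd <- generate_planted_dataset(n = 120, seed = 111,
                                 missing_ph_fraction = 0.15)
  spec <- estimator_spec("LR")
  res <- suppressWarnings(
    repeated_evaluation(pd$matrix, spec, n_repeats = 5, seed = 7))
  expect_s3_class(res, "ExperimentResult")
  expect_equal(nrow(res$metrics), 5L)
  expect_true(all(res$metrics$RMSE >= res$metrics$MAE))
  floor_mae <- sqrt(2 / pi) * pd$truth$noise_sd
  expect_lt(mean(res$metrics$MAE), 1.5 * floor_mae)
  expect_gt(mean(res$metrics$MAE), 0.7 * floor_mae)
  # same master seed, same result; different seed, different splits
  res2 <- suppressWarnings(
    repeated_evaluation(pd$matrix, spec, n_repeats = 5, seed = 7))
  expect_identical(res$metrics, res2$metrics)
  res3 <- suppressWarnings(
    repeated_evaluation(pd$matrix, spec, n_repeats = 5, seed = 8))
  expect_false(identical(res$metrics$MAE, res3$metrics$MAE))
})

test_that("radius scan reports one row per configuration and its argmin", {
  dir <- withr::local_tempdir()
  records <- generate_study_records(n_structures = 8, dir = dir, seed = 121)
  spec <- estimator_spec("RF", grid = data.frame(ntree = 50, max_depth = 3))
  grid <- radius_grid(r1 = c(8, 12), r2 = c(3, 5))
  scan <- suppressWarnings(
    radius_scan(records, spec, grid = grid, n_repeats = 2, seed = 3))
  expect_equal(nrow(scan$table), 4L)
  expect_equal(scan$best$mean_MAE, min(scan$table$mean_MAE))
  expect_length(scan$results, 4L)
})

test_that("pairwise Mann-Whitney comparison matches the U-statistic oracle", {
  mk <- function(name, values) structure(
    list(estimator = name, metrics = data.frame(MAE = values)),
    class = "ExperimentResult")
  a <- mk("A", 1:10); b <- mk("B", 101:110)
  rep_cmp <- pairwise_model_comparison(list(a, b))
  expect_lt(rep_cmp$p_values["A", "B"], 0.05)
  expect_true(rep_cmp$significant["A", "B"])
  # a sample against itself is not significant
  self_cmp <- pairwise_model_comparison(list(a, mk("A2", 1:10)))
  expect_gt(self_cmp$p_values["A", "A2"], 0.05)
  # identical constant samples get p = 1 by convention
  const_cmp <- pairwise_model_comparison(list(mk("C", rep(2, 10)),
                                              mk("D", rep(2, 10))))
  expect_equal(const_cmp$p_values["C", "D"], 1)
  # random pairs match the from-definition normal-approximation oracle
  for (s in 1:20) {
    set.seed(300 + s)
    x <- rnorm(10, 40, 5); y <- rnorm(10, 42, 5)
    got <- pairwise_model_comparison(list(mk("X", x), mk("Y", y)))
    expect_equal(got$p_values["X", "Y"], oracle_mw_p(x, y),
                 tolerance = 1e-9)
  }
})
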