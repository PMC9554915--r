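test_that("pH imputation uses the training mean only", {
  imp <- fit_imputer(c(7, 7, NA))
  expect_equal(imp$value, 7)
  imp2 <- fit_imputer(c(6, 8))
  expect_equal(apply_imputer(imp2, c(NA, 7.5)), c(7, 7.5))
  expect_equal(apply_imputer(imp2, c(5, 6)), c(5, 6))  # identity when complete
  expect_error(fit_imputer(c(NA_real_, NA_real_)), "all training pH")
})

test_that("the feature filter removes zero-variance and near-duplicate columns", {
  set.seed(61)
  X <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  X[, "f3"] <- 2                 # constant
  X[, "f6"] <- X[, "f2"]         # exact duplicate, later column dropped
  filt <- fit_feature_filter(X)
  expect_true("f3" %in% filt$dropped$feature)
  expect_equal(filt$dropped$reason[filt$dropped$feature == "f3"],
               "zero-variance")
  expect_true("f6" %in% filt$dropped$feature)
  expect_true("f2" %in% filt$kept)
  expect_match(filt$dropped$reason[filt$dropped$feature == "f6"],
               "correlated-with:f2")

  # surviving set agrees with an exhaustive pairwise-correlation oracle
  oracle_kept <- function(X, thr = 0.99) {
    nm <- colnames(X)
    keep <- character(0)
    for (j in nm) {
      if (stats::sd(X[, j]) == 0) next
      ok <- TRUE
      for (i in keep)
        if (abs(stats::cor(X[, i], X[, j])) > thr) { ok <- FALSE; break }
      if (ok) keep <- c(keep, j)
    }
    keep
  }
  for (s in 1:5) {
    set.seed(70 + s)
    Z <- matrix(rnorm(40 * 12), 40, 12,
                dimnames = list(NULL, paste0("g", 1:12)))
    Z[, 4] <- Z[, 1]
    Z[, 9] <- 0.999 * Z[, 2] + 0.001 * rnorm(40) * sd(Z[, 2])
    Z[, 11] <- -1
    f <- fit_feature_filter(Z)
    expect_identical(f$kept, oracle_kept(Z))
    kept_cor <- abs(stats::cor(Z[, f$kept]))
    diag(kept_cor) <- 0
    expect_lte(max(kept_cor), 0.99)
  }
})

test_that("standardization carries training statistics to other splits", {
  X <- matrix(c(0, 2, 4, 6), 2, 2, dimnames = list(NULL, c("a", "b")))
  std <- fit_standardizer(X)
  Xt <- apply_standardizer(std, X)
  expect_equal(unname(Xt[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(colMeans(Xt)), c(0, 0), tolerance = 1e-9)
  # test rows transformed with TRAIN stats differ from self-standardization
  Xtest <- matrix(c(10, 12, 1, 3), 2, 2, dimnames = list(NULL, c("a", "b")))
  with_train <- apply_standardizer(std, Xtest)
  with_self <- apply_standardizer(fit_standardizer(Xtest), Xtest)
  expect_false(isTRUE(all.equal(unname(with_train), unname(with_self))))
})

test_that("elastic-net selection brackets between no-penalty and all-penalty", {
  set.seed(81)
  n <- 120; p <- 20
  X <- scale(matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p))))
  y <- 3 * X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.1)
  expect_identical(elastic_net_select(X, y, alpha = 0), colnames(X))
  expect_warning(none <- elastic_net_select(X, y, alpha = 1e9, rho = 1),
                 "no features")
  expect_length(none, 0L)
  # support recovery with alpha tuned by inner CV at rho = 1
  alphas <- c(0.01, 0.1, 1, 10)
  cv_mae <- vapply(alphas, function(a) {
    fold <- rep(1:5, length.out = n)
    maes <- vapply(1:5, function(f) {
      tr <- fold != f
      sel <- suppressWarnings(
        elastic_net_select(X[tr, ], y[tr], alpha = a, rho = 1))
      if (length(sel) == 0) return(Inf)
      co <- stats::lm.fit(cbind(1, X[tr, sel, drop = FALSE]), y[tr])$coefficients
      pred <- cbind(1, X[!tr, sel, drop = FALSE]) %*% co
      mean(abs(y[!tr] - pred))
    }, numeric(1))
    mean(maes)
  }, numeric(1))
  best <- alphas[which.min(cv_mae)]
  sel <- elastic_net_select(X, y, alpha = best, rho = 1)
  expect_true(all(c("x1", "x2") %in% sel))
})

test_that("no test-row statistic leaks into the fitted state", {
  pd <- generate_planted_dataset(n = 80, seed = 91)
  X <- as.matrix(pd$matrix[, setdiff(names(pd$matrix), "E_m")])
  y <- pd$matrix$E_m
  train <- 1:60
  st_train_only <- fit_preprocessor(X[train, ], y[train],
                                    standardize = TRUE, en_alpha = 10,
                                    en_rho = 1)
  # refit with extra "test" rows present in the environment but unused
  st_again <- fit_preprocessor(X[train, ], y[train], standardize = TRUE,
                               en_alpha = 10, en_rho = 1)
  expect_identical(st_train_only$imputer, st_again$imputer)
  expect_identical(st_train_only$selected, st_again$selected)
  # state fitted on train+test rows differs, proving the state depends on
  # exactly the rows given
  st_leaky <- fit_preprocessor(X, y, standardize = TRUE, en_alpha = 10,
                               en_rho = 1)
  expect_false(identical(st_train_only$standardizer$center,
                         st_leaky$standardizer$center))
  # transformed training columns have mean 0 / sd 1 with train stats
  Xt <- apply_preprocessor(st_train_only, X[train, ])
  expect_lt(max(abs(colMeans(Xt))), 1e-9)
})
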