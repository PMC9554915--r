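# Six regression estimators behind one uniform surface. LR/SVR/KNR/GPR
# consume standardized, elastic-net-selected features; RF/XGB consume the
# imputed+filtered features directly and carry the max-depth grid {3,4,5}.

ESTIMATOR_NAMES <- c("LR", "GPR", "SVR", "KNR", "RF", "XGB")

.en_grid <- function() expand.grid(en_alpha = c(10, 100),
                                   en_rho = c(0.5, 0.75, 1))

.default_grid <- function(name) {
  switch(name,
    LR  = .en_grid(),
    SVR = merge(expand.grid(cost = c(0.1, 1, 10, 100),
                            epsilon = c(0.01, 0.1, 1)), .en_grid()),
    KNR = merge(expand.grid(k = c(3, 5, 7, 9, 11)), .en_grid()),
    GPR = merge(expand.grid(noise = 10^seq(-4, 0)), .en_grid()),
    RF  = expand.grid(ntree = c(100, 300, 500), max_depth = c(3, 4, 5)),
    XGB = expand.grid(eta = c(0.01, 0.05, 0.1), nrounds = c(100, 300, 500),
                      max_depth = c(3, 4, 5)))
}

# deterministic RBF bandwidth (median heuristic on squared distances)
.median_sigma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 150) round(seq(1, n, length.out = 150)) else seq_len(n)
  d2 <- stats::dist(X[idx, , drop = FALSE])^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med == 0) 1 else 1 / med
}

#' Estimator specification
#'
#' Bundles one of the six regression estimators (LR, GPR, SVR, KNR, RF,
#' XGB) with its hyperparameter grid and preprocessing needs. LR, SVR, KNR
#' and GPR are standardized and preceded by elastic-net feature selection
#' (the elastic-net \eqn{(\alpha, \rho)} pair is part of their grid); RF
#' and XGB consume unscaled features and carry the tree max-depth grid
#' \{3, 4, 5\}.
#'
#' @param name One of `"LR"`, `"GPR"`, `"SVR"`, `"KNR"`, `"RF"`, `"XGB"`.
#' @param grid Optional data frame overriding the documented default grid
#'   (one column per hyperparameter, one row per candidate).
#' @return Object of class `EstimatorSpec`.
#' @export
estimator_spec <- function(name, grid = NULL) {
  name <- match.arg(name, ESTIMATOR_NAMES)
  needs_std <- name %in% c("LR", "SVR", "KNR", "GPR")
  if (is.null(grid)) grid <- .default_grid(name)
  if (name %in% c("RF", "XGB") && !"max_depth" %in% names(grid))
    stop("tree estimators require a max_depth column in their grid",
         call. = FALSE)
  structure(list(name = name, grid = grid,
                 needs_standardization = needs_std,
                 uses_elastic_net = needs_std),
            class = "EstimatorSpec")
}

.fit_estimator <- function(name, X, y, params) {
  switch(name,
    LR = {
      Xi <- cbind(`(Intercept)` = 1, X)
      fit <- stats::lm.fit(Xi, y)
      co <- fit$coefficients
      co[is.na(co)] <- 0
      list(kind = "linear", coef = co)
    },
    SVR = list(kind = "svr",
               fit = e1071::svm(x = X, y = y, type = "eps-regression",
                                kernel = "radial", cost = params$cost,
                                epsilon = params$epsilon, scale = FALSE)),
    KNR = list(kind = "knn",
               fit = caret::knnreg(X, y, k = params$k)),
    GPR = list(kind = "gpr",
               fit = kernlab::gausspr(
                 x = X, y = y, kernel = "rbfdot",
                 kpar = list(sigma = .median_sigma(X)),
                 var = params$noise, variance.model = FALSE)),
    RF = list(kind = "rf",
              fit = randomForest::randomForest(
                x = X, y = y, ntree = params$ntree,
                # depth d maps to at most 2^d leaves, capped by the
                # training size on small data
                maxnodes = min(2L^params$max_depth, nrow(X)))),
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      list(kind = "xgb",
           fit = xgboost::xgb.train(
             params = list(max_depth = params$max_depth, eta = params$eta,
                           objective = "reg:squarederror", nthread = 1L),
             data = dtrain, nrounds = params$nrounds, verbose = 0))
    })
}

.predict_estimator <- function(model, X) {
  switch(model$kind,
    linear = as.numeric(cbind(1, X) %*% model$coef),
    svr = as.numeric(stats::predict(model$fit, X)),
    knn = as.numeric(stats::predict(model$fit, X)),
    gpr = as.numeric(kernlab::predict(model$fit, X)),
    rf = as.numeric(stats::predict(model$fit, X)),
    xgb = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X))))
}

#' Fit a full preprocessing + estimator pipeline
#'
#' Fits the estimator-appropriate preprocessing (pH imputation,
#' zero-variance/correlation filter, and for LR/SVR/KNR/GPR
#' standardization plus elastic-net selection with the \eqn{(\alpha,\rho)}
#' of `params`) on the training rows, then the estimator itself.
#'
#' @param X Training feature data frame / matrix (named columns).
#' @param y Training labels (mV).
#' @param spec An [estimator_spec()].
#' @param params One-row data frame / list of hyperparameters (a row of
#'   `spec$grid`).
#' @return Object of class `flavo_pipeline` with a [predict][stats::predict]
#'   method.
#' @export
fit_pipeline <- function(X, y, spec, params) {
  params <- as.list(params)
  pre <- fit_preprocessor(
    X, y, standardize = spec$needs_standardization,
    en_alpha = if (spec$uses_elastic_net) params$en_alpha else NULL,
    en_rho = if (spec$uses_elastic_net) params$en_rho else NULL)
  Xt <- apply_preprocessor(pre, X)
  model <- .fit_estimator(spec$name, Xt, y, params)
  structure(list(spec = spec, pre = pre, model = model, params = params,
                 feature_names = colnames(as.matrix(X))),
            class = "flavo_pipeline")
}

#' @export
predict.flavo_pipeline <- function(object, newdata, ...) {
  Xt <- apply_preprocessor(object$pre, newdata)
  .predict_estimator(object$model, Xt)
}

#' @export
print.flavo_pipeline <- function(x, ...) {
  cat("flavo_pipeline:", x$spec$name, "on",
      length(x$pre$selected), "selected features\n")
  invisible(x)
}
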