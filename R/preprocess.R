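# Train-set-aware preprocessing. Every fit_* function learns its state from
# training rows only; the matching apply step uses stored state, so no test
# statistic can leak into the fit.

#' Fit the pH imputer
#'
#' Stores the arithmetic mean of the non-missing training pH values; the
#' transform replaces missing pH in any split with this value.
#'
#' @param train_pH Numeric vector of training pH values (may contain `NA`).
#' @return Object of class `ph_imputer` with element `value`.
#' @export
fit_imputer <- function(train_pH) {
  if (all(is.na(train_pH)))
    stop("cannot fit pH imputer: all training pH values missing",
         call. = FALSE)
  structure(list(value = mean(train_pH, na.rm = TRUE)),
            class = "ph_imputer")
}

#' @rdname fit_imputer
#' @param imputer A fitted `ph_imputer`.
#' @param pH Vector of pH values to transform.
#' @export
apply_imputer <- function(imputer, pH) {
  pH[is.na(pH)] <- imputer$value
  pH
}

#' Fit the invariant / correlated feature filter
#'
#' First drops zero-variance training columns, then scans feature pairs in
#' column order and drops the later column of any pair whose absolute
#' Pearson correlation on the training rows exceeds `threshold` with an
#' already retained column. Reasons are recorded per dropped feature.
#'
#' @param X_train Numeric matrix or data frame of training features.
#' @param threshold Absolute Pearson correlation above which the later
#'   column of a pair is dropped (study value 0.99).
#' @return Object of class `feature_filter` with `kept` (character) and
#'   `dropped` (data frame feature/reason).
#' @export
fit_feature_filter <- function(X_train, threshold = 0.99) {
  X <- as.matrix(X_train)
  stopifnot(nrow(X) >= 2L)
  nm <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  dropped <- data.frame(feature = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  zv <- nm[sds == 0]
  if (length(zv))
    dropped <- rbind(dropped, data.frame(feature = zv,
                                         reason = "zero-variance"))
  keep <- setdiff(nm, zv)
  if (length(keep) >= 2L) {
    cm <- abs(stats::cor(X[, keep, drop = FALSE]))
    retained <- keep[1]
    for (j in keep[-1]) {
      hit <- retained[cm[retained, j] > threshold]
      if (length(hit)) {
        dropped <- rbind(dropped, data.frame(
          feature = j, reason = paste0("correlated-with:", hit[1])))
      } else retained <- c(retained, j)
    }
    keep <- retained
  }
  structure(list(kept = keep, dropped = dropped, threshold = threshold),
            class = "feature_filter")
}

#' @rdname fit_feature_filter
#' @param filter A fitted `feature_filter`.
#' @param X Feature matrix / data frame to transform.
#' @export
apply_feature_filter <- function(filter, X) {
  as.matrix(X)[, filter$kept, drop = FALSE]
}

#' Fit the feature standardizer
#'
#' Stores per-feature training mean and standard deviation; the transform
#' centers and scales any split with the training statistics. Used only by
#' the LR/SVR/KNR/GPR branch — tree ensembles consume unscaled features.
#'
#' @param X_train Numeric matrix (zero-variance columns already removed).
#' @return Object of class `standardizer` with `center` and `scale`.
#' @export
fit_standardizer <- function(X_train) {
  X <- as.matrix(X_train)
  structure(list(center = colMeans(X), scale = apply(X, 2, stats::sd)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param standardizer A fitted `standardizer`.
#' @param X Matrix to transform with the stored training statistics.
#' @export
apply_standardizer <- function(standardizer, X) {
  scale(as.matrix(X), center = standardizer$center,
        scale = standardizer$scale)
}

#' Elastic-net feature selection
#'
#' Fits the elastic-net cost
#' \deqn{\frac{1}{2n}\|y - Xw\|_2^2 + \alpha\rho\|w\|_1 +
#'   \frac{\alpha(1-\rho)}{2}\|w\|_2^2}
#' by coordinate descent (via \pkg{glmnet}, whose objective matches this
#' parameterisation with `lambda = alpha`, `alpha = rho`) and returns the
#' features with nonzero coefficients. `alpha = 0` reduces to ordinary
#' least squares, selecting all features. An empty selection triggers a
#' warning and falls back to all input features.
#'
#' @param X_train_std Standardized training feature matrix.
#' @param y_train Training labels (mV).
#' @param alpha Regularisation weight \eqn{\alpha \ge 0} (study values 10
#'   and 100).
#' @param rho L1/L2 mixing weight \eqn{\rho \in [0, 1]} (study values 0.5,
#'   0.75, 1).
#' @return Character vector of selected feature names.
#' @export
elastic_net_select <- function(X_train_std, y_train, alpha = 10, rho = 0.5) {
  X <- as.matrix(X_train_std)
  stopifnot(alpha >= 0, rho >= 0, rho <= 1, nrow(X) >= 2L)
  if (alpha == 0) return(colnames(X))
  if (stats::sd(y_train) == 0) {
    # centred constant response: every penalised coefficient is exactly 0
    warning("elastic net selected no features", call. = FALSE)
    return(character(0))
  }
  fit <- glmnet::glmnet(X, y_train, alpha = rho, lambda = alpha,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-10)
  w <- as.numeric(stats::coef(fit))[-1]
  sel <- colnames(X)[w != 0]
  if (length(sel) == 0L)
    warning("elastic net selected no features", call. = FALSE)
  sel
}

#' Fit the full preprocessing pipeline on training rows
#'
#' Order is fixed: pH imputation, zero-variance / high-correlation
#' filtering, then — for estimators that need it — standardization and
#' elastic-net feature selection; tree ensembles receive the
#' imputed+filtered features untouched.
#'
#' @param X_train Training feature data frame / matrix (may include a
#'   `pH` column with missing values).
#' @param y_train Training labels (needed when `en_alpha` is given).
#' @param standardize Standardize features (LR/SVR/KNR/GPR branch)?
#' @param en_alpha,en_rho Elastic-net parameters; `NULL` skips selection.
#' @param cor_threshold Correlation-filter threshold.
#' @return Object of class `preprocess_state`; apply with
#'   [apply_preprocessor()].
#' @export
fit_preprocessor <- function(X_train, y_train = NULL, standardize = FALSE,
                             en_alpha = NULL, en_rho = NULL,
                             cor_threshold = 0.99) {
  X <- as.matrix(X_train)
  imputer <- NULL
  if ("pH" %in% colnames(X) && !all(is.na(X[, "pH"]))) {
    imputer <- fit_imputer(X[, "pH"])
    X[, "pH"] <- apply_imputer(imputer, X[, "pH"])
  }
  filter <- fit_feature_filter(X, threshold = cor_threshold)
  X <- apply_feature_filter(filter, X)
  standardizer <- NULL
  selected <- colnames(X)
  if (standardize) {
    standardizer <- fit_standardizer(X)
    Xs <- apply_standardizer(standardizer, X)
    if (!is.null(en_alpha)) {
      selected <- elastic_net_select(Xs, y_train, en_alpha,
                                     if (is.null(en_rho)) 0.5 else en_rho)
      if (length(selected) == 0L) selected <- colnames(X)
    }
  }
  structure(list(imputer = imputer, filter = filter,
                 standardizer = standardizer, selected = selected,
                 standardize = standardize),
            class = "preprocess_state")
}

#' @rdname fit_preprocessor
#' @param state A fitted `preprocess_state`.
#' @param X Feature matrix / data frame of any split.
#' @export
apply_preprocessor <- function(state, X) {
  X <- as.matrix(X)
  if (!is.null(state$imputer) && "pH" %in% colnames(X))
    X[, "pH"] <- apply_imputer(state$imputer, X[, "pH"])
  X <- apply_feature_filter(state$filter, X)
  if (state$standardize)
    X <- apply_standardizer(state$standardizer, X)
  X[, state$selected, drop = FALSE]
}

#' Plain-text audit report of a preprocessing state
#' @param state A `preprocess_state`.
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly when written to `path`.
#' @export
preprocess_report <- function(state, path = NULL) {
  lines <- c(
    sprintf("pH imputation value: %s",
            if (is.null(state$imputer)) "none" else
              format(state$imputer$value)),
    sprintf("dropped features (%d):", nrow(state$filter$dropped)),
    sprintf("  %s [%s]", state$filter$dropped$feature,
            state$filter$dropped$reason),
    sprintf("selected features (%d):", length(state$selected)),
    paste0("  ", state$selected))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
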