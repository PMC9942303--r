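#' Fit a covariate residualizer
#'
#' Regresses each feature on the covariates by ordinary least squares with an
#' intercept, \eqn{\hat X_{ik} = \hat\beta_0 + \sum_q Z_{kq}\hat\beta_{iq}},
#' and stores the coefficients so that residuals
#' \eqn{e_{ik} = X_{ik} - \hat X_{ik}} can be computed on the fitting data or
#' on new samples (e.g. held-out cross-validation folds) without refitting.
#' On the fitting data the residuals of every feature have mean zero and are
#' exactly orthogonal to (hence uncorrelated with) every covariate column —
#' this is what decorrelates features from clinical variables before
#' top-scoring-pair selection. Categorical covariates with more than two
#' levels must be pre-encoded as 0/1 indicator columns by the caller.
#'
#' @inheritParams score_pairs
#' @param covariates Covariate specification: either a character vector of
#'   numeric columns of `data` (binary covariates coded 0/1), or a separate
#'   data frame with a `sample_id` column that is matched against `data`.
#' @param features Feature columns to residualize. Default: every numeric
#'   column except the id and covariate columns.
#' @return An object of class `"residualizer"` holding the `p x (q+1)`
#'   coefficient matrix (intercept first), covariate and feature names.
#'   Apply it with [predict()][predict.residualizer]; [residualize()] does
#'   fit-and-apply in one call. [tidy()] returns the coefficients.
#' @examples
#' sim <- simulate_study1(seed = 1)
#' rz <- fit_residualizer(sim, covariates = "Z",
#'                        features = c("X1", "X2", "X3", "X4"))
#' resid_data <- predict(rz, sim)
#' cor(resid_data$X1, sim$Z)   # 0 up to rounding
#' @export
fit_residualizer <- function(data, covariates, features = NULL,
                             id_col = "sample_id") {
  Z <- resolve_covariates(data, covariates, id_col)
  feats <- resolve_features(data, features,
                            exclude = colnames(Z), id_col = id_col)
  X <- feature_matrix(data, feats, id_col)
  D <- cbind(`(Intercept)` = 1, Z)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    dropped <- colnames(D)[qd$pivot[(qd$rank + 1):ncol(D)]]
    abort(paste0("covariate design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qd, X)  # (q+1) x p
  structure(
    list(
      coefficients = t(beta),
      covariate_ids = colnames(Z),
      feature_ids = feats
    ),
    class = "residualizer"
  )
}

#' @noRd
resolve_covariates <- function(data, covariates, id_col = "sample_id") {
  if (is.data.frame(covariates)) {
    idc <- resolve_id_col(covariates, id_col)
    if (is.null(idc)) abort("covariate data frame must contain a sample id column")
    ids <- sample_ids(data, id_col)
    m <- match(ids, as.character(covariates[[idc]]))
    if (anyNA(m)) {
      abort(paste0("samples missing from covariate table: ",
                   paste(head(ids[is.na(m)], 5), collapse = ", ")))
    }
    cov_df <- covariates[m, setdiff(names(covariates), idc), drop = FALSE]
  } else {
    missing <- setdiff(covariates, names(data))
    if (length(missing) > 0) {
      abort(paste0("covariate column(s) not found: ", paste(missing, collapse = ", ")))
    }
    cov_df <- as.data.frame(data)[, covariates, drop = FALSE]
  }
  Z <- as.matrix(cov_df)
  if (!is.numeric(Z)) abort("covariates must be numeric (pre-encode categorical covariates as 0/1 indicators)")
  if (anyNA(Z)) abort("covariates contain missing values")
  Z
}

#' Apply a fitted residualizer
#'
#' @param object A `"residualizer"` from [fit_residualizer()].
#' @param newdata Data frame containing the model's feature and covariate
#'   columns (matched by name; extra columns are passed through).
#' @param covariates Optional separate covariate data frame, as in
#'   [fit_residualizer()]; by default covariate columns are taken from
#'   `newdata`.
#' @param ... Unused.
#' @return `newdata` with each model feature column replaced by its residual
#'   \eqn{e = X - \hat X}. On samples not used for fitting the residuals are
#'   generally not mean zero.
#' @export
predict.residualizer <- function(object, newdata, covariates = NULL, ...) {
  missing <- setdiff(object$feature_ids, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("feature column(s) missing from newdata: ",
                 paste(missing, collapse = ", ")))
  }
  Z <- if (is.null(covariates)) {
    resolve_covariates(newdata, object$covariate_ids)
  } else {
    resolve_covariates(newdata, covariates)
  }
  if (!identical(colnames(Z), object$covariate_ids)) {
    abort(paste0("covariate columns do not match the fitted model: expected ",
                 paste(object$covariate_ids, collapse = ", ")))
  }
  X <- feature_matrix(newdata, object$feature_ids)
  fitted <- cbind(1, Z) %*% t(object$coefficients)
  out <- newdata
  out[object$feature_ids] <- as.data.frame(X - fitted)
  tibble::as_tibble(out)
}

#' Residualize features on covariates in one step
#'
#' Convenience wrapper: [fit_residualizer()] on `data` followed by
#' [predict()][predict.residualizer] on the same data. Use the two-step form
#' when train/test hygiene matters (fit on training folds, apply to test
#' folds).
#'
#' @inheritParams fit_residualizer
#' @return A tibble like `data` with feature columns replaced by OLS
#'   residuals.
#' @export
residualize <- function(data, covariates, features = NULL,
                        id_col = "sample_id") {
  rz <- fit_residualizer(data, covariates, features, id_col)
  predict(rz, data,
          covariates = if (is.data.frame(covariates)) covariates else NULL)
}

#' @export
print.residualizer <- function(x, ...) {
  cat(sprintf("Residualizer: %d features ~ intercept + %s\n",
              length(x$feature_ids), paste(x$covariate_ids, collapse = " + ")))
  invisible(x)
}

#' @describeIn fit_residualizer Coefficients in long form (`feature`, `term`,
#'   `estimate`).
#' @param x A `"residualizer"`.
#' @export
tidy.residualizer <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    feature = rep(rownames(co), times = ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.vector(co)
  )
}
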