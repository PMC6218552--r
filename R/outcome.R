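#' L1 feature selection with cross-validated sparsity choice
#'
#' Fits the propensity-weighted lasso path of follow-up GDI on standardized
#' candidate features and picks the penalty by the one-standard-error rule:
#' the largest penalty (sparsest model) whose mean cross-validated weighted
#' error is within one standard error of the minimum. Weights enter both the
#' fold fits and the fold scoring. Standardization is internal to selection
#' only; downstream refits are in natural units.
#'
#' @param x Numeric matrix or data frame of candidate features (one arm,
#'   follow-up limbs only).
#' @param y Follow-up GDI.
#' @param weights Inverse-propensity weights, see [ipw_weights()].
#' @param n_folds Cross-validation folds, default 10.
#' @param penalty_grid Optional decreasing penalty sequence; the default is
#'   100 log-spaced values spanning 4 decades down from the smallest penalty
#'   that zeroes every coefficient.
#' @param seed Integer seed fixing the fold assignment.
#' @return An object of class `semls_selection`: `penalty_grid`, `cv_error`,
#'   `cv_se`, `penalty_min`, `penalty_chosen` (the one-SE choice),
#'   `selected` (features with nonzero coefficients at the chosen penalty),
#'   `n_selected`, `dropped_constant`.
#' @export
select_features <- function(x, y, weights = rep(1, length(y)), n_folds = 10,
                            penalty_grid = NULL, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < n_folds) stop("fewer limbs than cross-validation folds")
  constant <- apply(x, 2, function(col) stats::sd(col) == 0)
  dropped <- colnames(x)[constant]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    x <- x[, !constant, drop = FALSE]
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(x)))
  args <- list(x = x, y = y, weights = weights, foldid = foldid,
               family = "gaussian", alpha = 1, standardize = TRUE)
  if (is.null(penalty_grid)) {
    args$nlambda <- 100
    args$lambda.min.ratio <- 1e-4
  } else {
    args$lambda <- penalty_grid
  }
  cv <- do.call(glmnet::cv.glmnet, args)
  beta <- stats::coef(cv, s = "lambda.1se")
  selected <- rownames(beta)[as.vector(beta != 0)]
  selected <- setdiff(selected, "(Intercept)")
  structure(
    list(penalty_grid = cv$lambda, cv_error = cv$cvm, cv_se = cv$cvsd,
         penalty_min = cv$lambda.min, penalty_chosen = cv$lambda.1se,
         selected = selected, n_selected = length(selected),
         dropped_constant = dropped),
    class = "semls_selection"
  )
}

#' Weighted least-squares outcome model
#'
#' Refits the selected features by weighted least squares: coefficients
#' solve the weighted normal equations minimizing the total weighted squared
#' error of follow-up GDI. Residual variance is the weighted residual sum of
#' squares over `n - p - 1`, and the classical coefficient covariance is
#' that variance times the inverse weighted Gram matrix; a
#' heteroscedasticity-robust sandwich covariance is available via
#' `vcov_type = "sandwich"`. Training feature means and SDs (unweighted) are
#' stored so standardized effect sizes and model cards can be derived.
#'
#' @param x Feature matrix or data frame restricted to the selected features.
#' @param y Follow-up GDI.
#' @param weights Positive case weights.
#' @param arm Optional arm label stored with the model.
#' @param vcov_type `"classical"` or `"sandwich"` (HC0).
#' @return An object of class `semls_outcome_model`: `arm`, `features`,
#'   `coefficients` (including `"(Intercept)"`, natural units), `vcov`,
#'   `sigma2` (residual variance, GDI^2), `feature_means`, `feature_sds`,
#'   `n`, `vcov_type`, `weights`.
#' @export
#' @examples
#' m <- fit_weighted_ols(data.frame(x = c(0, 1, 2)), c(0, 1, 4))
#' coef(m)
fit_weighted_ols <- function(x, y, weights = rep(1, length(y)), arm = NULL,
                             vcov_type = c("classical", "sandwich")) {
  vcov_type <- match.arg(vcov_type)
  x <- as.data.frame(x)
  p <- ncol(x)
  if (nrow(x) <= p + 1) stop("need more limbs than coefficients")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  design <- cbind("(Intercept)" = 1, as.matrix(x))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  dat <- data.frame(.y = y, x, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat, weights = weights)
  sigma2 <- sum(weights * stats::residuals(fit)^2) / (nrow(x) - p - 1)
  vc <- if (vcov_type == "classical") {
    sigma2 * summary(fit)$cov.unscaled
  } else {
    sandwich::vcovHC(fit, type = "HC0")
  }
  coefs <- stats::coef(fit)
  names(coefs)[1] <- "(Intercept)"
  dimnames(vc) <- list(names(coefs), names(coefs))
  structure(
    list(arm = arm, features = colnames(x), coefficients = coefs, vcov = vc,
         sigma2 = sigma2,
         feature_means = vapply(x, mean, numeric(1)),
         feature_sds = vapply(x, stats::sd, numeric(1)),
         n = nrow(x), vcov_type = vcov_type, weights = weights),
    class = "semls_outcome_model"
  )
}

#' @export
coef.semls_outcome_model <- function(object, ...) object$coefficients

#' @export
print.semls_outcome_model <- function(x, ...) {
  cat("Weighted linear model of follow-up GDI",
      if (!is.null(x$arm)) paste0(" (", x$arm, " arm)"), "\n", sep = "")
  cat("  n = ", x$n, ", residual SD = ", round(sqrt(x$sigma2), 2),
      " GDI\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Standardized effect sizes of an outcome model
#'
#' The change in predicted follow-up GDI per one training-data standard
#' deviation of each feature: `effect = coefficient * SD(feature)`, with
#' standard deviation `SD(feature) * sqrt(vcov_jj)`.
#'
#' @param model A `semls_outcome_model`.
#' @return A `data.frame`: `feature`, `coefficient`, `coefficient_sd`,
#'   `feature_sd`, `effect`, `effect_sd`.
#' @export
standardized_effects <- function(model) {
  stopifnot(inherits(model, "semls_outcome_model"))
  f <- model$features
  coefs <- model$coefficients[f]
  coef_sd <- sqrt(diag(model$vcov)[f])
  data.frame(
    feature = f,
    coefficient = unname(coefs),
    coefficient_sd = unname(coef_sd),
    feature_sd = unname(model$feature_sds[f]),
    effect = unname(coefs * model$feature_sds[f]),
    effect_sd = unname(coef_sd * model$feature_sds[f]),
    stringsAsFactors = FALSE
  )
}

#' Predict follow-up GDI with a prediction interval
#'
#' Point prediction `intercept + sum(coef * feature)` with a normal-quantile
#' prediction interval for an individual limb's outcome,
#' `point +/- z * sqrt(x' V x + sigma2)`, combining coefficient uncertainty
#' and residual variance.
#'
#' @param model A `semls_outcome_model`.
#' @param newdata Data frame (or named list/vector for one limb) covering
#'   the model's selected features.
#' @param level Interval coverage, default 0.95.
#' @return A `data.frame` with columns `fit`, `lwr`, `upr`.
#' @export
predict_with_interval <- function(model, newdata, level = 0.95) {
  stopifnot(inherits(model, "semls_outcome_model"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  missing <- setdiff(model$features, names(newdata))
  if (length(missing)) {
    stop("missing selected feature(s): ", paste(missing, collapse = ", "))
  }
  X <- cbind(1, as.matrix(newdata[, model$features, drop = FALSE]))
  beta <- model$coefficients[c("(Intercept)", model$features)]
  fit <- drop(X %*% beta)
  V <- model$vcov[c("(Intercept)", model$features),
                  c("(Intercept)", model$features)]
  pred_var <- rowSums((X %*% V) * X) + model$sigma2
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(fit = fit, lwr = fit - z * sqrt(pred_var),
             upr = fit + z * sqrt(pred_var))
}
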