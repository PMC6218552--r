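#' Variance explained
#'
#' `1 - RSS/TSS` with the total sum of squares about the mean of the
#' observed values; can be negative out of sample.
#'
#' @param y_true Observed follow-up GDI.
#' @param y_pred Predicted follow-up GDI.
#' @return Scalar R-squared in `(-Inf, 1]`.
#' @export
r2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0) stop("R^2 undefined: y_true is constant")
  1 - sum((y_true - y_pred)^2) / tss
}

#' Post-hoc classification at the GDI-80 rule
#'
#' A follow-up GDI of at least 80 indicates gait within two standard
#' deviations of typical gait. Both truth and prediction are thresholded at
#' `threshold_gdi` (ties classified positive) and agreement rates reported,
#' with truth >= threshold as the positive class.
#'
#' @param y_true Observed follow-up GDI.
#' @param y_pred Predicted follow-up GDI.
#' @param threshold_gdi GDI threshold, default 80.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`.
#' @export
classify_gdi80 <- function(y_true, y_pred, threshold_gdi = 80) {
  classification_rates(y_true >= threshold_gdi, y_pred >= threshold_gdi)
}

#' ROC curve and AUC over the predicted-GDI threshold
#'
#' Sweeps the classification threshold across all distinct scores (predicted
#' GDI), classifying scores `>=` threshold as positive, and traces true
#' positive rate against false positive rate from (0, 0) to (1, 1). AUC is
#' the trapezoidal area, which equals the pairwise concordance probability
#' with ties counted one half.
#'
#' @param y_true_binary Logical (or 0/1) truth, e.g. observed GDI >= 80.
#' @param y_score Continuous score, e.g. predicted GDI.
#' @return A list of class `semls_roc`: `points` (`data.frame` with `fpr`,
#'   `tpr`, monotone from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(y_true_binary, y_score) {
  truth <- as.logical(y_true_binary)
  stopifnot(length(truth) == length(y_score))
  if (all(truth) || !any(truth)) {
    stop("ROC undefined: only one class present in the truth")
  }
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  ord <- order(y_score, decreasing = TRUE)
  truth <- truth[ord]
  score <- y_score[ord]
  # one ROC point per distinct threshold (all tied scores flip together)
  last <- which(!duplicated(score, fromLast = TRUE))
  tpr <- c(0, cumsum(truth)[last] / n_pos, 1)
  fpr <- c(0, cumsum(!truth)[last] / n_neg, 1)
  points <- unique(data.frame(fpr = fpr, tpr = tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "semls_roc")
}

#' Evaluate an outcome model on a test cohort
#'
#' Restricts the test cohort to follow-up limbs of the model's arm, predicts
#' follow-up GDI, and reports variance explained, the GDI-80 post-hoc
#' classification rates, and the ROC/AUC over the predicted-GDI threshold.
#' Evaluation is unweighted; inverse-propensity weights are a training
#' device only.
#'
#' @param model A `semls_outcome_model` (with a non-`NULL` `arm` to filter
#'   by arm; otherwise all follow-up limbs are used).
#' @param cohort Test cohort `data.frame`.
#' @param threshold_gdi GDI threshold for the post-hoc classification.
#' @return A list of class `semls_eval`: `arm`, `r_squared`, `accuracy`,
#'   `sensitivity`, `specificity`, `roc_points`, `auc`, `n_evaluated`.
#' @export
evaluate_outcome_model <- function(model, cohort, threshold_gdi = 80) {
  keep <- cohort$followup_available
  if (!is.null(model$arm)) keep <- keep & cohort$arm == model$arm
  test <- cohort[keep, , drop = FALSE]
  if (nrow(test) < 2) stop("too few follow-up limbs to evaluate")
  pred <- predict_with_interval(model, test)$fit
  cls <- classify_gdi80(test$gdi_followup, pred, threshold_gdi)
  roc <- tryCatch(roc_auc(test$gdi_followup >= threshold_gdi, pred),
                  error = function(e) NULL)
  structure(
    list(arm = model$arm,
         r_squared = r2(test$gdi_followup, pred),
         accuracy = cls$accuracy, sensitivity = cls$sensitivity,
         specificity = cls$specificity,
         roc_points = if (!is.null(roc)) roc$points else NULL,
         auc = if (!is.null(roc)) roc$auc else NA_real_,
         n_evaluated = nrow(test)),
    class = "semls_eval"
  )
}
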