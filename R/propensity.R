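#' Fit the propensity-for-surgery model
#'
#' Estimates each limb's probability of receiving single-event multilevel
#' surgery from pre-treatment features with a random forest (100 trees by
#' default) whose class priors are fixed at 50/50 to correct for arm
#' imbalance. Limbs without follow-up are included: the propensity model
#' uses the full cohort even though the outcome regressions later drop
#' follow-up-missing limbs.
#'
#' @param cohort Cohort `data.frame` containing both arms.
#' @param features Character vector of predictor columns; defaults to all
#'   pre-treatment feature columns.
#' @param n_trees Number of trees.
#' @param seed Integer seed controlling the forest's randomness.
#' @return An object of class `semls_propensity`: the fitted forest plus
#'   `features`, `n_trees`, `seed`, and training arm counts.
#' @export
fit_propensity <- function(cohort, features = feature_columns(cohort),
                           n_trees = 100, seed = NULL) {
  arm <- cohort$arm
  if (nlevels(droplevels(factor(arm))) < 2) {
    stop("cohort must contain both surgery and control limbs")
  }
  arm <- factor(arm, levels = c("control", "surgery"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  forest <- randomForest::randomForest(
    x = cohort[, features, drop = FALSE], y = arm,
    ntree = n_trees, classwt = c(control = 0.5, surgery = 0.5)
  )
  structure(
    list(forest = forest, features = features, n_trees = n_trees,
         seed = seed, class_priors = c(control = 0.5, surgery = 0.5),
         n_train = as.vector(table(arm)[c("control", "surgery")])),
    class = "semls_propensity"
  )
}

#' Propensity scores for a cohort
#'
#' With `cohort = NULL`, returns out-of-bag probability estimates for the
#' training limbs (each limb scored only by trees that did not see it, so
#' training-set scores are not overfit); otherwise ordinary forest
#' predictions for new limbs.
#'
#' @param model A `semls_propensity` model.
#' @param cohort Optional cohort `data.frame` to score.
#' @return Numeric vector of surgery probabilities in \[0, 1\].
#' @export
propensity_scores <- function(model, cohort = NULL) {
  stopifnot(inherits(model, "semls_propensity"))
  if (is.null(cohort)) {
    p <- stats::predict(model$forest, type = "prob")[, "surgery"]
  } else {
    p <- stats::predict(model$forest,
                        newdata = cohort[, model$features, drop = FALSE],
                        type = "prob")[, "surgery"]
  }
  # a limb in-bag for every tree has no out-of-bag vote
  p[!is.finite(p)] <- 0.5
  unname(p)
}

#' Inverse-propensity regression weights
#'
#' Each limb is weighted by the reciprocal of the probability of the
#' treatment it actually received: `1/p` for surgery limbs and `1/(1-p)` for
#' control limbs, after clipping `p` into `clip`. Surgery limbs that looked
#' unlikely to receive surgery are thereby upweighted in the surgery model,
#' and vice versa for control limbs. Weights are optionally renormalized to
#' mean 1 within each arm, which leaves weighted-least-squares coefficients
#' unchanged and only rescales the reported weighted residual sums.
#'
#' @param p_hat Per-limb surgery probability.
#' @param arm Per-limb arm label (`"control"`/`"surgery"` vector or factor).
#' @param clip Length-2 clipping bounds applied to `p_hat`.
#' @param normalize Renormalize to mean 1 within each arm.
#' @return Positive numeric weight vector.
#' @export
#' @examples
#' ipw_weights(c(0.25, 0.25), c("surgery", "control"), normalize = FALSE)
ipw_weights <- function(p_hat, arm, clip = c(0.05, 0.95), normalize = TRUE) {
  if (any(p_hat < 0 | p_hat > 1, na.rm = TRUE)) {
    stop("p_hat must lie in [0, 1]")
  }
  stopifnot(length(clip) == 2, clip[1] <= clip[2])
  p <- pmin(pmax(p_hat, clip[1]), clip[2])
  surgery <- as.character(arm) == "surgery"
  w <- ifelse(surgery, 1 / p, 1 / (1 - p))
  if (normalize) {
    w[surgery] <- w[surgery] / mean(w[surgery])
    w[!surgery] <- w[!surgery] / mean(w[!surgery])
  }
  w
}

#' Propensity-stratified covariate balance table
#'
#' Bins limbs into equal-width propensity strata over \[0, 1\] and reports,
#' per bin and feature, the per-arm count, mean and median together with the
#' between-arm standardized mean difference
#' `(mean_surgery - mean_control) / pooled SD`. Arms with similar propensity
#' should show similar pre-treatment features; a shrinking within-bin gap
#' relative to the unstratified gap is the balance diagnostic.
#'
#' @param cohort Cohort `data.frame`.
#' @param p_hat Per-limb propensity scores.
#' @param features Feature columns to tabulate.
#' @param n_bins Number of equal-width bins over \[0, 1\].
#' @return A `data.frame` with one row per bin x feature: `bin`, `bin_lo`,
#'   `bin_hi`, `feature`, `n_control`, `n_surgery`, `mean_control`,
#'   `mean_surgery`, `median_control`, `median_surgery`, `smd`. Empty
#'   bin/arm cells have count 0 and `NA` statistics.
#' @export
stratified_balance <- function(cohort, p_hat, features = c("gdi"),
                               n_bins = 5) {
  stopifnot(length(p_hat) == nrow(cohort))
  bin <- pmin(floor(p_hat * n_bins) + 1L, n_bins)
  surgery <- cohort$arm == "surgery"
  rows <- list()
  for (b in seq_len(n_bins)) {
    for (f in features) {
      xc <- cohort[[f]][bin == b & !surgery]
      xs <- cohort[[f]][bin == b & surgery]
      pooled <- sqrt((stats::var(xs) + stats::var(xc)) / 2)
      smd <- if (length(xs) > 1 && length(xc) > 1 && is.finite(pooled) &&
                 pooled > 0) (mean(xs) - mean(xc)) / pooled else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, bin_lo = (b - 1) / n_bins, bin_hi = b / n_bins,
        feature = f, n_control = length(xc), n_surgery = length(xs),
        mean_control = if (length(xc)) mean(xc) else NA_real_,
        mean_surgery = if (length(xs)) mean(xs) else NA_real_,
        median_control = if (length(xc)) stats::median(xc) else NA_real_,
        median_surgery = if (length(xs)) stats::median(xs) else NA_real_,
        smd = smd, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Classification performance of a propensity model
#'
#' Classifies limbs as surgery when the propensity score reaches
#' `threshold` (surgery is the positive class) and reports accuracy,
#' sensitivity and specificity.
#'
#' @param model A `semls_propensity` model.
#' @param cohort Labelled cohort to evaluate on.
#' @param threshold Probability cut, default 0.5 (the natural cut under
#'   50/50 class priors).
#' @param oob Use out-of-bag scores (appropriate when `cohort` is the
#'   training set); otherwise ordinary predictions.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_propensity <- function(model, cohort, threshold = 0.5, oob = FALSE) {
  p <- if (oob) propensity_scores(model) else propensity_scores(model, cohort)
  classification_rates(cohort$arm == "surgery", p >= threshold)
}

# accuracy / sensitivity / specificity of a binary prediction
classification_rates <- function(truth, predicted) {
  list(
    accuracy = mean(predicted == truth),
    sensitivity = if (any(truth)) mean(predicted[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!predicted[!truth]) else NA_real_
  )
}
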