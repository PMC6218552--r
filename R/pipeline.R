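#' Split a cohort into training and testing halves
#'
#' Disjoint, exhaustive partition stratified by arm, so both arms populate
#' both halves; the split is fixed once and shared by all pipeline
#' repetitions.
#'
#' @param cohort Cohort `data.frame`.
#' @param train_fraction Training fraction, default 0.7.
#' @param seed Integer seed.
#' @return List with `train` and `test` cohort `data.frame`s.
#' @export
split_cohort <- function(cohort, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (a in levels(factor(cohort$arm))) {
    idx <- which(cohort$arm == a)
    n_train <- round(length(idx) * train_fraction)
    if (n_train < 1 || n_train >= length(idx)) {
      stop("cohort too small to populate both halves in arm ", a)
    }
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  list(train = cohort[sort(train_idx), , drop = FALSE],
       test = cohort[-sort(train_idx), , drop = FALSE])
}

#' Run the model-building pipeline once
#'
#' One pass of the counterfactual modelling pipeline on a fixed
#' train/test split: fit the propensity-for-surgery forest on all training
#' limbs (including those without follow-up), derive out-of-bag
#' inverse-propensity weights, then per arm run l1 feature selection and
#' the weighted least-squares refit on follow-up limbs only, and evaluate
#' both models on the held-out test limbs.
#'
#' @param train,test Cohorts from [split_cohort()].
#' @param seed Integer seed controlling the training-phase randomness
#'   (forest and cross-validation folds).
#' @param features Candidate feature columns; default all pre-treatment
#'   features.
#' @param n_trees Propensity forest size.
#' @param n_folds Cross-validation folds for selection.
#' @param clip Propensity clipping bounds for the weights.
#' @param vcov_type Covariance estimator for the refits.
#' @return A list of class `semls_run`: `propensity` (model),
#'   `propensity_eval` (test-set rates), `weights`, `selection` and
#'   `models` (per-arm), `evaluation` (per-arm `semls_eval` on the test
#'   set).
#' @export
run_pipeline_once <- function(train, test, seed = 1L,
                              features = feature_columns(train),
                              n_trees = 100, n_folds = 10,
                              clip = c(0.05, 0.95),
                              vcov_type = "classical") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- as.integer(seed)
  prop <- stage("propensity", fit_propensity(
    train, features = features, n_trees = n_trees, seed = seed))
  p_hat <- stage("propensity", propensity_scores(prop))
  w <- stage("weights", ipw_weights(p_hat, train$arm, clip = clip))

  selection <- list()
  models <- list()
  evaluation <- list()
  for (a in c("surgery", "control")) {
    keep <- train$arm == a & train$followup_available
    x <- train[keep, features, drop = FALSE]
    y <- train$gdi_followup[keep]
    sel <- stage(paste0("selection_", a), select_features(
      x, y, weights = w[keep], n_folds = n_folds,
      seed = seed + match(a, c("surgery", "control"))))
    fit <- stage(paste0("fit_", a), fit_weighted_ols(
      x[, sel$selected, drop = FALSE], y, weights = w[keep], arm = a,
      vcov_type = vcov_type))
    selection[[a]] <- sel
    models[[a]] <- fit
    evaluation[[a]] <- stage(paste0("evaluate_", a),
                             evaluate_outcome_model(fit, test))
  }
  structure(
    list(propensity = prop,
         propensity_eval = evaluate_propensity(prop, test),
         weights = w, selection = selection, models = models,
         evaluation = evaluation, seed = seed),
    class = "semls_run"
  )
}

#' Repeat the pipeline and aggregate a model consensus
#'
#' Repeats [run_pipeline_once()] on the fixed train/test split, varying
#' only the training-phase randomness (forest seed and cross-validation
#' fold assignment) with per-repetition seeds `base_seed + 1 .. + n_reps`,
#' and aggregates: per-feature inclusion frequencies and the consensus
#' feature set (features selected in at least `consensus_level` of
#' repetitions), median selected-model size, coefficient and
#' standardized-effect means/SDs over the repetitions where each feature
#' was selected, and the distributions of test R-squared, GDI-80 accuracy
#' and AUC per arm. Individual repetition failures are skipped with a
#' warning; more than 10% failures aborts.
#'
#' @param train,test Cohorts from [split_cohort()].
#' @param n_reps Number of repetitions (default 1000).
#' @param base_seed Base integer seed.
#' @param consensus_level Inclusion-frequency cutoff for the consensus
#'   feature set, default 0.8.
#' @param ... Passed to [run_pipeline_once()].
#' @return A list of class `semls_repetition` with one entry per arm:
#'   `inclusion` (named frequencies), `consensus` (feature names),
#'   `median_model_size`, `coefficients` (`data.frame` of per-feature mean/
#'   SD of coefficients and standardized effects, over selecting
#'   repetitions), `metrics` (`data.frame` with one row per repetition:
#'   `r_squared`, `accuracy`, `auc`), plus `n_reps`, `n_failed`.
#' @export
repeat_and_summarize <- function(train, test, n_reps = 1000, base_seed = 1L,
                                 consensus_level = 0.8, ...) {
  stopifnot(n_reps >= 2)
  runs <- vector("list", n_reps)
  failures <- character(0)
  for (i in seq_len(n_reps)) {
    runs[[i]] <- tryCatch(
      run_pipeline_once(train, test, seed = as.integer(base_seed) + i, ...),
      error = function(e) {
        failures <<- c(failures, conditionMessage(e))
        NULL
      })
  }
  if (length(failures) > n_reps / 10) {
    stop("more than 10% of repetitions failed; first error: ", failures[1])
  }
  if (length(failures)) {
    warning(length(failures), " repetition(s) failed and were skipped")
  }
  runs <- Filter(Negate(is.null), runs)
  features <- feature_columns(train)

  per_arm <- lapply(c("surgery", "control"), function(a) {
    sel_sets <- lapply(runs, function(r) r$selection[[a]]$selected)
    inclusion <- vapply(features, function(f) {
      mean(vapply(sel_sets, function(s) f %in% s, logical(1)))
    }, numeric(1))
    coef_rows <- lapply(features, function(f) {
      hits <- vapply(sel_sets, function(s) f %in% s, logical(1))
      if (!any(hits)) return(NULL)
      cc <- vapply(runs[hits], function(r) r$models[[a]]$coefficients[[f]],
                   numeric(1))
      ee <- vapply(runs[hits], function(r) {
        eff <- standardized_effects(r$models[[a]])
        eff$effect[eff$feature == f]
      }, numeric(1))
      data.frame(feature = f, inclusion = mean(hits),
                 coefficient_mean = mean(cc),
                 coefficient_sd = stats::sd(cc),
                 effect_mean = mean(ee), effect_sd = stats::sd(ee),
                 stringsAsFactors = FALSE)
    })
    metrics <- data.frame(
      r_squared = vapply(runs, function(r) r$evaluation[[a]]$r_squared,
                         numeric(1)),
      accuracy = vapply(runs, function(r) r$evaluation[[a]]$accuracy,
                        numeric(1)),
      auc = vapply(runs, function(r) r$evaluation[[a]]$auc, numeric(1))
    )
    list(inclusion = inclusion,
         consensus = names(inclusion)[inclusion >= consensus_level],
         median_model_size = stats::median(
           vapply(sel_sets, length, integer(1))),
         coefficients = do.call(rbind, coef_rows),
         metrics = metrics)
  })
  names(per_arm) <- c("surgery", "control")
  structure(c(per_arm, list(n_reps = n_reps, n_failed = length(failures),
                            consensus_level = consensus_level)),
            class = "semls_repetition")
}

#' @export
print.semls_repetition <- function(x, ...) {
  cat("Repeated pipeline summary (", x$n_reps, " repetitions, ",
      x$n_failed, " failed)\n", sep = "")
  for (a in c("surgery", "control")) {
    cat("\n", a, " arm: median model size ", x[[a]]$median_model_size,
        ", consensus features (>= ", 100 * x$consensus_level, "%): ",
        paste(x[[a]]$consensus, collapse = ", "), "\n", sep = "")
    cat("  mean test R^2 ", round(mean(x[[a]]$metrics$r_squared), 3),
        ", mean GDI-80 accuracy ", round(mean(x[[a]]$metrics$accuracy), 3),
        ", mean AUC ", round(mean(x[[a]]$metrics$auc, na.rm = TRUE), 3),
        "\n", sep = "")
  }
  invisible(x)
}
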