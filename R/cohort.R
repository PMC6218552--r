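#' Generate a synthetic limb cohort with known counterfactual outcomes
#'
#' Draws continuous gait and exam features from a correlated multivariate
#' normal, quadriplegia as a Bernoulli flag, and nuisance features as
#' independent standard normals; computes each limb's surgery propensity from
#' the configured logistic model; assigns exactly
#' `round(n_limbs * surgery_fraction)` limbs to surgery by ranking
#' propensity-perturbed uniform draws; evaluates both counterfactual
#' follow-up GDIs `true_gdi_surgery` and `true_gdi_control` from the
#' arm-specific linear models with independent Gaussian residuals; and marks
#' follow-up availability by exact-count sampling within each arm at the
#' configured retention rates. The observed `gdi_followup` equals the
#' assigned arm's counterfactual where follow-up is available and is `NA`
#' otherwise.
#'
#' The same `(config, seed)` pair always reproduces the identical table.
#'
#' @param config A `semls_config`, typically from [default_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `data.frame` with one row per limb: `limb_id`, `patient_id`,
#'   the feature columns, `true_propensity`, `arm` (factor,
#'   control/surgery), `followup_available`, `gdi_followup`,
#'   `true_gdi_surgery`, `true_gdi_control`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_config(n_limbs = 200), seed = 42)
#' table(cohort$arm)
generate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  n <- as.integer(config$n_limbs)
  set.seed(as.integer(seed))

  continuous <- names(config$feature_sds)
  R <- config$feature_correlations[continuous, continuous]
  ev <- eigen(R, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R)) %*% t(ev$vectors)
  Z <- matrix(stats::rnorm(n * length(continuous)), n) %*% A
  X <- sweep(sweep(Z, 2, config$feature_sds[continuous], "*"),
             2, config$feature_means[continuous], "+")
  colnames(X) <- continuous

  quadriplegia <- stats::rbinom(n, 1, config$quadriplegia_prob)

  n_nuis <- config$n_nuisance_features
  nuisance <- NULL
  if (n_nuis > 0) {
    nuisance <- matrix(stats::rnorm(n * n_nuis), n)
    colnames(nuisance) <- sprintf("nuisance_%02d", seq_len(n_nuis))
  }

  features <- cbind(X, quadriplegia = quadriplegia, nuisance)

  propensity <- stats::plogis(linear_predictor(
    features, config$propensity_coefficients))

  # exact-count assignment: the round(n * fraction) limbs with the largest
  # propensity-perturbed draws receive surgery
  n_surgery <- round(n * config$surgery_fraction)
  u <- stats::runif(n)
  arm <- factor(ifelse(rank(propensity - u, ties.method = "first") > n - n_surgery,
                       "surgery", "control"),
                levels = c("control", "surgery"))

  true_gdi_surgery <- linear_predictor(features, config$outcome_coefficients_surgery) +
    stats::rnorm(n, 0, config$noise_sd_surgery)
  true_gdi_control <- linear_predictor(features, config$outcome_coefficients_control) +
    stats::rnorm(n, 0, config$noise_sd_control)

  followup_available <- logical(n)
  for (a in c("control", "surgery")) {
    idx <- which(arm == a)
    retain <- round(length(idx) *
                      (1 - config[[paste0("followup_missing_prob_", a)]]))
    followup_available[idx[order(stats::runif(length(idx)))[seq_len(retain)]]] <- TRUE
  }

  gdi_followup <- ifelse(arm == "surgery", true_gdi_surgery, true_gdi_control)
  gdi_followup[!followup_available] <- NA_real_

  data.frame(
    limb_id = sprintf("L%06d", seq_len(n)),
    patient_id = sprintf("P%06d", seq_len(n)),
    features,
    true_propensity = propensity,
    arm = arm,
    followup_available = followup_available,
    gdi_followup = gdi_followup,
    true_gdi_surgery = true_gdi_surgery,
    true_gdi_control = true_gdi_control,
    stringsAsFactors = FALSE
  )
}

# intercept + sum(coef * feature) for coefficients named over columns of x
linear_predictor <- function(x, coefficients) {
  slopes <- coefficients[setdiff(names(coefficients), "(Intercept)")]
  missing <- setdiff(names(slopes), colnames(x))
  if (length(missing)) {
    stop("features missing from data: ", paste(missing, collapse = ", "))
  }
  intercept <- if ("(Intercept)" %in% names(coefficients)) {
    coefficients[["(Intercept)"]]
  } else 0
  drop(intercept + x[, names(slopes), drop = FALSE] %*% slopes)
}

#' True per-limb surgery effect of a synthetic cohort
#'
#' The generator's hidden ground truth: the difference between each limb's
#' counterfactual follow-up GDI with and without surgery. Only defined for
#' synthetic cohorts, where both counterfactuals are recorded.
#'
#' @param cohort A cohort `data.frame` from [generate_cohort()].
#' @return Numeric vector, `true_gdi_surgery - true_gdi_control`.
#' @export
true_effect <- function(cohort) {
  if (!all(c("true_gdi_surgery", "true_gdi_control") %in% names(cohort)) ||
      anyNA(cohort$true_gdi_surgery) || anyNA(cohort$true_gdi_control)) {
    stop("counterfactual outcomes absent: not a synthetic cohort")
  }
  cohort$true_gdi_surgery - cohort$true_gdi_control
}

#' Feature columns of a cohort table
#'
#' All columns except identifiers, treatment labels and (counterfactual)
#' outcomes — the pre-treatment predictors available to the propensity and
#' outcome models.
#'
#' @param cohort A cohort `data.frame`.
#' @return Character vector of column names.
#' @export
feature_columns <- function(cohort) {
  reserved <- c("limb_id", "patient_id", "true_propensity", "arm",
                "followup_available", "gdi_followup",
                "true_gdi_surgery", "true_gdi_control")
  setdiff(names(cohort), reserved)
}

#' Write or read a cohort table as CSV
#'
#' One row per limb, header row with canonical feature names; missing
#' follow-up GDI is encoded as an empty field. Reading restores the arm
#' factor and logical follow-up flag.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("arm" %in% names(cohort)) {
    cohort$arm <- factor(cohort$arm, levels = c("control", "surgery"))
  }
  if ("followup_available" %in% names(cohort)) {
    cohort$followup_available <- as.logical(cohort$followup_available)
  }
  cohort
}
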