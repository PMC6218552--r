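# shared fixtures; expensive objects are built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# default cohort at the published size, fixed seed
default_cohort <- function() {
  cached("default_cohort", function() generate_cohort(default_config(), seed = 101))
}

# outcome model object holding exactly a config's published coefficients,
# with zero coefficient covariance and residual variance `sigma2`
config_model <- function(config, arm, sigma2 = 0) {
  coefs <- config[[paste0("outcome_coefficients_", arm)]]
  features <- setdiff(names(coefs), "(Intercept)")
  k <- length(features) + 1
  vc <- matrix(0, k, k, dimnames = list(names(coefs), names(coefs)))
  structure(
    list(arm = arm, features = features, coefficients = coefs, vcov = vc,
         sigma2 = sigma2,
         feature_means = stats::setNames(rep(0, length(features)), features),
         feature_sds = stats::setNames(rep(1, length(features)), features),
         n = NA_integer_, vcov_type = "classical", weights = NULL),
    class = "semls_outcome_model"
  )
}

# parameter-recovery experiment: 20,000 limbs per arm from the default
# generating models, propensity + IPW, weighted OLS on the true feature set
recovery_run <- function() {
  cached("recovery_run", function() {
    cfg <- default_config(n_limbs = 40000, surgery_fraction = 0.5, seed = 404)
    cohort <- generate_cohort(cfg)
    prop <- fit_propensity(cohort, seed = 404)
    w <- ipw_weights(propensity_scores(prop), cohort$arm)
    models <- lapply(c("surgery", "control"), function(a) {
      keep <- cohort$arm == a & cohort$followup_available
      feats <- setdiff(names(cfg[[paste0("outcome_coefficients_", a)]]),
                       "(Intercept)")
      fit_weighted_ols(cohort[keep, feats, drop = FALSE],
                       cohort$gdi_followup[keep], weights = w[keep], arm = a)
    })
    names(models) <- c("surgery", "control")
    list(config = cfg, cohort = cohort, models = models)
  })
}

# brute-force AUC: pairwise concordance with ties counted one half
concordance_auc <- function(truth, score) {
  pos <- score[as.logical(truth)]
  neg <- score[!as.logical(truth)]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}
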