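#' Export or import an outcome model as a portable model card
#'
#' A model card is a flat text/CSV pair that fully determines predictions
#' and intervals — the portable analog of a downloadable clinical
#' worksheet: `<prefix>_card.yaml` holds scalar metadata (arm, n, residual
#' variance, covariance type), `<prefix>_coefficients.csv` the intercept and
#' per-feature coefficients with training means/SDs and standardized
#' effects, and `<prefix>_covariance.csv` the coefficient covariance matrix.
#'
#' @param model A `semls_outcome_model`.
#' @param prefix Path prefix for the three files.
#' @return `write_model_card()` returns the three paths invisibly;
#'   `read_model_card()` returns a `semls_outcome_model` (without training
#'   weights).
#' @export
write_model_card <- function(model, prefix) {
  stopifnot(inherits(model, "semls_outcome_model"))
  paths <- paste0(prefix, c("_card.yaml", "_coefficients.csv",
                            "_covariance.csv"))
  yaml::write_yaml(
    list(arm = model$arm, n = model$n, sigma2 = model$sigma2,
         vcov_type = model$vcov_type, features = as.list(model$features)),
    paths[1], precision = 15
  )
  eff <- standardized_effects(model)
  coef_table <- rbind(
    data.frame(feature = "(Intercept)",
               coefficient = unname(model$coefficients["(Intercept)"]),
               coefficient_sd = sqrt(model$vcov["(Intercept)", "(Intercept)"]),
               feature_mean = NA_real_, feature_sd = NA_real_,
               effect = NA_real_, effect_sd = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(feature = eff$feature, coefficient = eff$coefficient,
               coefficient_sd = eff$coefficient_sd,
               feature_mean = unname(model$feature_means[eff$feature]),
               feature_sd = eff$feature_sd, effect = eff$effect,
               effect_sd = eff$effect_sd, stringsAsFactors = FALSE)
  )
  utils::write.csv(coef_table, paths[2], row.names = FALSE)
  vc <- as.data.frame(model$vcov)
  utils::write.csv(cbind(term = rownames(model$vcov), vc), paths[3],
                   row.names = FALSE)
  invisible(paths)
}

#' @rdname write_model_card
#' @export
read_model_card <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_card.yaml"))
  coefs <- utils::read.csv(paste0(prefix, "_coefficients.csv"),
                           stringsAsFactors = FALSE)
  vc_raw <- utils::read.csv(paste0(prefix, "_covariance.csv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  vc <- as.matrix(vc_raw[, -1, drop = FALSE])
  rownames(vc) <- vc_raw$term
  features <- unlist(meta$features)
  body <- coefs[coefs$feature != "(Intercept)", ]
  structure(
    list(arm = meta$arm, features = features,
         coefficients = stats::setNames(coefs$coefficient, coefs$feature),
         vcov = vc, sigma2 = meta$sigma2,
         feature_means = stats::setNames(body$feature_mean, body$feature),
         feature_sds = stats::setNames(body$feature_sd, body$feature),
         n = meta$n, vcov_type = meta$vcov_type, weights = NULL),
    class = "semls_outcome_model"
  )
}
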