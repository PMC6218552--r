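#' Per-limb counterfactual effect of surgery
#'
#' Predicts each limb's follow-up GDI under both treatment paths — the
#' surgery model and the natural-progression (control) model — with 95%
#' prediction intervals, and reports the effect size as their difference
#' (surgery minus control; positive means surgery is expected to improve
#' gait). The two intervals are reported separately: the arm models are fit
#' independently, so no joint covariance for the difference is available.
#'
#' @param newdata Data frame of limb features covering both models'
#'   selected features; optional columns `limb_id` and `arm` are carried
#'   through (an `arm` column also triggers adequacy flagging).
#' @param surgery_model,control_model `semls_outcome_model` objects (or
#'   model cards read back via [read_model_card()]).
#' @param level Interval coverage.
#' @param meaningful_threshold GDI-point threshold for a clinically
#'   meaningful improvement, default 5.
#' @return A `data.frame` with one row per limb: `pred_gdi_surgery`,
#'   `lwr_surgery`, `upr_surgery`, `pred_gdi_control`, `lwr_control`,
#'   `upr_control`, `effect`, plus `limb_id`, `observed_arm` and
#'   `adequacy_flag` when an `arm` column is present.
#' @export
estimate_effect <- function(newdata, surgery_model, control_model,
                            level = 0.95, meaningful_threshold = 5) {
  ps <- predict_with_interval(surgery_model, newdata, level = level)
  pc <- predict_with_interval(control_model, newdata, level = level)
  out <- data.frame(
    pred_gdi_surgery = ps$fit, lwr_surgery = ps$lwr, upr_surgery = ps$upr,
    pred_gdi_control = pc$fit, lwr_control = pc$lwr, upr_control = pc$upr,
    effect = ps$fit - pc$fit
  )
  if (!is.null(newdata$limb_id)) out <- cbind(limb_id = newdata$limb_id, out)
  if (!is.null(newdata$arm)) {
    out$observed_arm <- as.character(newdata$arm)
    out$adequacy_flag <- adequacy_flag(out$effect, out$observed_arm,
                                       meaningful_threshold)
  }
  out
}

#' Treatment-adequacy flag
#'
#' Labels each limb by comparing its estimated surgery effect with the
#' treatment it actually received: a control limb whose estimated effect
#' reaches the meaningful threshold was potentially under-treated, otherwise
#' it was (appropriately) conservatively treated; a surgery limb with a
#' non-positive estimated effect was potentially over-treated, one reaching
#' the threshold was appropriately surgically treated, and one in between is
#' indeterminate.
#'
#' @param effect Estimated effect size(s), GDI points.
#' @param arm Observed arm label(s), `"control"`/`"surgery"`.
#' @param meaningful_threshold Clinically meaningful improvement, default 5.
#' @return Factor with levels `under_treated`, `appropriately_treated`,
#'   `over_treated`, `conservatively_treated`, `indeterminate`.
#' @export
#' @examples
#' adequacy_flag(c(8, -1, 2.5), c("control", "surgery", "surgery"))
adequacy_flag <- function(effect, arm, meaningful_threshold = 5) {
  surgery <- as.character(arm) == "surgery"
  flag <- ifelse(!surgery,
                 ifelse(effect >= meaningful_threshold,
                        "under_treated", "conservatively_treated"),
                 ifelse(effect <= 0, "over_treated",
                        ifelse(effect >= meaningful_threshold,
                               "appropriately_treated", "indeterminate")))
  factor(flag, levels = c("under_treated", "appropriately_treated",
                          "over_treated", "conservatively_treated",
                          "indeterminate"))
}

#' Cohort-level summary of estimated surgery effects
#'
#' Reports the proportion of limbs with a strictly positive estimated
#' effect, the proportion with at least a clinically meaningful effect, the
#' arm split among limbs with a meaningful effect, a histogram of effect
#' sizes, and (when adequacy flags are present) per-arm adequacy
#' proportions: the share of control limbs flagged under-treated and of
#' surgery limbs flagged over-treated.
#'
#' @param estimates Output of [estimate_effect()] (requires at least the
#'   `effect` column; arm-based summaries need `observed_arm`).
#' @param meaningful_threshold GDI points, default 5.
#' @param breaks Histogram break specification passed to [graphics::hist()].
#' @return A list of class `semls_effect_summary`: `n`, `prop_positive`,
#'   `prop_meaningful`, `prop_meaningful_by_arm`, `prop_under_treated`
#'   (of control limbs), `prop_over_treated` (of surgery limbs),
#'   `histogram` (`data.frame` of bin edges and counts).
#' @export
cohort_effect_summary <- function(estimates, meaningful_threshold = 5,
                                  breaks = "Sturges") {
  effect <- estimates$effect
  if (is.null(effect) || !length(effect)) stop("no effect estimates supplied")
  h <- graphics::hist(effect, breaks = breaks, plot = FALSE)
  meaningful <- effect >= meaningful_threshold
  out <- list(
    n = length(effect),
    prop_positive = mean(effect > 0),
    prop_meaningful = mean(meaningful),
    prop_meaningful_by_arm = NULL,
    prop_under_treated = NA_real_,
    prop_over_treated = NA_real_,
    histogram = data.frame(lower = utils::head(h$breaks, -1),
                           upper = utils::tail(h$breaks, -1),
                           count = h$counts)
  )
  arm <- estimates$observed_arm
  if (!is.null(arm)) {
    if (any(meaningful)) {
      out$prop_meaningful_by_arm <-
        prop.table(table(factor(arm[meaningful],
                                levels = c("control", "surgery"))))
    }
    control <- arm == "control"
    out$prop_under_treated <- mean(effect[control] >= meaningful_threshold)
    out$prop_over_treated <- mean(effect[!control] <= 0)
  }
  structure(out, class = "semls_effect_summary")
}

#' @export
print.semls_effect_summary <- function(x, ...) {
  cat("Estimated surgery effect over", x$n, "limbs\n")
  cat(sprintf("  positive effect: %.1f%%\n", 100 * x$prop_positive))
  cat(sprintf("  clinically meaningful effect: %.1f%%\n",
              100 * x$prop_meaningful))
  if (!is.na(x$prop_under_treated)) {
    cat(sprintf("  control limbs potentially under-treated: %.1f%%\n",
                100 * x$prop_under_treated))
    cat(sprintf("  surgery limbs potentially over-treated: %.1f%%\n",
                100 * x$prop_over_treated))
  }
  invisible(x)
}
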