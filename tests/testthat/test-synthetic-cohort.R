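test_that("default configuration encodes the published outcome models", {
  cfg <- default_config()
  expect_equal(cfg$outcome_coefficients_surgery[["gdi"]], 0.27)
  expect_equal(cfg$outcome_coefficients_surgery[["(Intercept)"]], 48.03)
  expect_equal(cfg$outcome_coefficients_control[["gdi"]], 0.57)
  expect_equal(cfg$outcome_coefficients_control[["(Intercept)"]], 19.99)
  # implied feature SD = standardized effect / coefficient
  expect_equal(cfg$feature_sds[["gdi"]], 2.58 / 0.27, tolerance = 1e-12)
  expect_equal(cfg$feature_sds[["gdi"]], 9.56, tolerance = 1e-3)
  # cross-check against the control-arm ratio: same feature, consistent scale
  expect_equal(5.40 / 0.57, cfg$feature_sds[["gdi"]], tolerance = 0.01)
  # binary-feature SD formula: sqrt(p(1-p)) = published effect ratio
  p <- cfg$quadriplegia_prob
  expect_equal(sqrt(p * (1 - p)), 0.84 / 2.01, tolerance = 1e-12)
  expect_equal(p, 0.226, tolerance = 1e-2)
  expect_lt(p, 0.5) # lower root
  expect_equal(cfg$surgery_fraction, 1424 / 2333)
  # confounding loads negatively on first-visit GDI
  expect_lt(cfg$propensity_coefficients[["gdi"]], 0)
  expect_silent(validate_config(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(validate_config(default_config(surgery_fraction = 1.2)),
               "probabilities")
  cfg <- default_config()
  cfg$feature_sds[["gdi"]] <- -1
  expect_error(validate_config(cfg), "positive")
  cfg <- default_config()
  cfg$feature_correlations["gdi", "gdi_contra"] <- 0.9 # asymmetric now
  expect_error(validate_config(cfg), "symmetric")
  cfg <- default_config()
  cfg$feature_correlations["gdi", "gdi_contra"] <-
    cfg$feature_correlations["gdi_contra", "gdi"] <- 1.5
  expect_error(validate_config(cfg), "semi-definite")
  cfg <- default_config()
  cfg$outcome_coefficients_surgery[["nuisance_01"]] <- 0.3
  expect_error(validate_config(cfg), "nuisance")
  expect_error(generate_cohort(default_config(n_limbs = 0)), "positive count")
})

test_that("default cohort reproduces the published arm and follow-up counts", {
  cohort <- default_cohort()
  expect_equal(nrow(cohort), 2333)
  expect_equal(sum(cohort$arm == "surgery"), 1424)
  expect_equal(sum(cohort$arm == "control"), 909)
  expect_equal(sum(cohort$followup_available & cohort$arm == "surgery"), 1133)
  expect_equal(sum(cohort$followup_available & cohort$arm == "control"), 582)
  # follow-up GDI present iff available, and equals the assigned arm's truth
  expect_true(all(is.na(cohort$gdi_followup) == !cohort$followup_available))
  avail <- cohort[cohort$followup_available, ]
  expect_equal(avail$gdi_followup,
               ifelse(avail$arm == "surgery", avail$true_gdi_surgery,
                      avail$true_gdi_control))
})

test_that("identical config and seed give byte-identical CSV exports", {
  cfg <- default_config(n_limbs = 300)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg, seed = 7), f1)
  write_cohort(generate_cohort(cfg, seed = 7), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed gives a different cohort
  expect_false(identical(generate_cohort(cfg, seed = 8),
                         generate_cohort(cfg, seed = 7)))
  # CSV round-trip preserves types
  back <- read_cohort(f1)
  expect_s3_class(back$arm, "factor")
  expect_type(back$followup_available, "logical")
})

test_that("unconfounded assignment yields balanced arms", {
  cfg <- default_config(n_limbs = 4000)
  cfg$propensity_coefficients[] <- 0
  cohort <- generate_cohort(cfg, seed = 21)
  expect_equal(sum(cohort$arm == "surgery"), round(4000 * cfg$surgery_fraction))
  # with flat propensity the arms have identical feature distributions
  smd <- function(f) {
    s <- cohort[[f]][cohort$arm == "surgery"]
    c <- cohort[[f]][cohort$arm == "control"]
    (mean(s) - mean(c)) / sqrt((var(s) + var(c)) / 2)
  }
  for (f in c("gdi", "speed", "strength")) expect_lt(abs(smd(f)), 0.08)
})

test_that("confounded assignment reproduces the observed severity gap", {
  cohort <- default_cohort()
  gap <- mean(cohort$gdi[cohort$arm == "control"]) -
    mean(cohort$gdi[cohort$arm == "surgery"])
  expect_gt(gap, 0)          # surgery limbs are more severely affected
  expect_equal(gap, 4.4, tolerance = 0.25) # observed cohort gap, GDI points
})

test_that("assignment is marginally calibrated to the true propensity", {
  cohort <- cached("cohort20k", function() {
    generate_cohort(default_config(n_limbs = 20000), seed = 55)
  })
  bins <- cut(cohort$true_propensity,
              stats::quantile(cohort$true_propensity, 0:5 / 5),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    rate <- mean(cohort$arm[idx] == "surgery")
    expected <- mean(cohort$true_propensity[idx])
    se <- sqrt(expected * (1 - expected) / sum(idx))
    expect_lt(abs(rate - expected), 4 * se + 0.01)
  }
})

test_that("true effect matches the generating models", {
  cohort <- default_cohort()
  expect_equal(true_effect(cohort),
               cohort$true_gdi_surgery - cohort$true_gdi_control)
  # closed-form mean effect: difference of the two linear predictors at the
  # configured feature means
  cfg <- default_config()
  lp_at_means <- function(coefs) {
    feats <- setdiff(names(coefs), "(Intercept)")
    means <- c(cfg$feature_means, quadriplegia = cfg$quadriplegia_prob)
    coefs[["(Intercept)"]] + sum(coefs[feats] * means[feats])
  }
  analytic <- lp_at_means(cfg$outcome_coefficients_surgery) -
    lp_at_means(cfg$outcome_coefficients_control)
  big <- cached("cohort20k", function() {
    generate_cohort(default_config(n_limbs = 20000), seed = 55)
  })
  # per-limb effects have SD ~9.4 (linear predictors plus both noise draws),
  # so the mean over 20,000 limbs carries ~0.07 Monte-Carlo error
  expect_lt(abs(mean(true_effect(big)) - analytic), 0.2)
  # non-synthetic records are refused
  real <- cohort[, setdiff(names(cohort), "true_gdi_control")]
  expect_error(true_effect(real), "not a synthetic cohort")
})

test_that("noise-free counterfactuals equal the published linear predictors", {
  cfg <- default_config(n_limbs = 50)
  cfg$noise_sd_surgery <- cfg$noise_sd_control <- 1e-9
  cohort <- generate_cohort(cfg, seed = 3)
  cs <- cfg$outcome_coefficients_surgery
  cc <- cfg$outcome_coefficients_control
  for (i in c(1, 17)) {
    row <- cohort[i, ]
    hand_s <- cs[["(Intercept)"]] +
      sum(vapply(setdiff(names(cs), "(Intercept)"),
                 function(f) cs[[f]] * row[[f]], numeric(1)))
    hand_c <- cc[["(Intercept)"]] +
      sum(vapply(setdiff(names(cc), "(Intercept)"),
                 function(f) cc[[f]] * row[[f]], numeric(1)))
    expect_equal(row$true_gdi_surgery, hand_s, tolerance = 1e-6)
    expect_equal(true_effect(row), hand_s - hand_c, tolerance = 1e-6)
  }
})

test_that("within-arm regression on true features recovers the generator", {
  cohort <- cached("cohort50k", function() {
    generate_cohort(default_config(n_limbs = 50000), seed = 77)
  })
  cfg <- default_config()
  for (a in c("surgery", "control")) {
    coefs <- cfg[[paste0("outcome_coefficients_", a)]]
    feats <- setdiff(names(coefs), "(Intercept)")
    idx <- cohort$arm == a & cohort$followup_available
    fit <- stats::lm(stats::reformulate(feats, "gdi_followup"),
                     data = cohort[idx, ])
    se <- sqrt(diag(stats::vcov(fit)))
    est <- stats::coef(fit)
    for (term in names(coefs)) {
      expect_lt(abs(est[[term]] - coefs[[term]]), 3 * se[[term]])
    }
    # noise calibration: the true model explains ~41% / ~40% within its arm
    target <- if (a == "surgery") 0.41 else 0.40
    noise_sd <- cfg[[paste0("noise_sd_", a)]]
    r2_true <- 1 - noise_sd^2 / stats::var(cohort$gdi_followup[idx])
    expect_equal(r2_true, target, tolerance = 0.03)
  }
})
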