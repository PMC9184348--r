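test_that("partial-likelihood fit matches the brute-force oracle on small fixtures", {
  d <- tiny_surv_fixture()
  fit <- fit_cox(d, "x", horizons = c(1, 3, 5))
  oracle <- breslow_oracle_beta(d$follow_up, d$ckd, d$x)
  expect_equal(fit$beta, oracle, tolerance = 1e-6)
  expect_equal(fit$log_partial_likelihood,
               breslow_logpl(oracle, d$follow_up, d$ckd, d$x),
               tolerance = 1e-8)

  # second fixture without ties and with a continuous covariate
  d2 <- data.frame(follow_up = c(0.5, 1.2, 2.3, 3.1, 4.4, 6.0),
                   ckd = c(1, 0, 1, 1, 0, 1),
                   x = c(0.2, -1.1, 0.7, 1.5, -0.4, 0.1))
  fit2 <- fit_cox(d2, "x")
  oracle2 <- breslow_oracle_beta(d2$follow_up, d2$ckd, d2$x)
  expect_equal(fit2$beta, oracle2, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- tiny_surv_fixture()
  d$z <- 1
  expect_error(fit_cox(d, "z"), "constant")
  expect_error(fit_cox(d, "missing_col"), "not in data")
  d0 <- d; d0$ckd <- 0
  expect_error(fit_cox(d0, "x"), "event")
})

test_that("baseline survival is a proper non-increasing curve at the mean profile", {
  d <- derived_default_cohort()
  fit <- fit_cox(d, score_terms)
  expect_true(all(diff(fit$baseline_survival) <= 0))
  expect_true(all(fit$baseline_survival > 0 & fit$baseline_survival <= 1))
  sf <- survival::survfit(fit$model)
  expect_true(all(diff(sf$surv) <= 1e-12))
  expect_lte(max(sf$surv), 1)
  # hazard ratios are consistent with betas and CI midpoints
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-12)
  expect_equal(sqrt(fit$hr_lower * fit$hr_upper), fit$hr, tolerance = 1e-10)
})

test_that("crude hazard ratios anchor the reference stratum at 1", {
  d <- derived_default_cohort()
  hr <- crude_hazard_ratios(d, "duration_cat")
  expect_equal(hr$stratum[1], "0")
  expect_equal(hr$hr[1], 1)
  expect_true(all(is.na(hr[1, c("lower", "upper", "p")])))
  expect_equal(nrow(hr), nlevels(d$duration_cat))
})

test_that("crude hazard ratio recovers a known stroke effect at large n", {
  # single-factor scenario: only stroke raises the hazard, at a prevalence
  # high enough to estimate a crude HR precisely, with the baseline scaled
  # for a realistic event rate once the other effects are absent
  b <- cohort_spec()$true_coefficients * 0
  b["stroke"] <- 0.77
  spec <- cohort_spec(n_subjects = 20000, seed = 21,
                      covariate_params = list(comorbidity = c(
                        stroke = 0.10, hypertension = 0.361,
                        coronary_artery_disease = 0.15,
                        carotid_atherosclerosis = 0.071, retinopathy = 0.031,
                        hyperlipidemia = 0.217, hyperuricemia = 0.134)),
                      true_coefficients = b,
                      baseline_hazard = list(shape = 1.4, scale = 40))
  d <- suppressWarnings(derive_covariates(generate_cohort(spec)))
  hr <- crude_hazard_ratios(d, "stroke")
  expect_equal(hr$hr[2], exp(0.77), tolerance = 0.08)
  expect_true(hr$lower[2] < exp(0.77) && exp(0.77) < hr$upper[2])
})

test_that("parameter recovery is nearly unbiased at large n", {
  # bias = mean estimate minus truth over replicates; stroke prevalence is
  # raised to 10% so the rare-exposure coefficient is estimated precisely
  # enough for an absolute 0.05 bias bound to be a meaningful check
  truth_names <- c("age", "sexmale", "duration_cat1-5", "duration_cat6-10",
                   "duration_cat11-15", "duration_cat16-20",
                   "duration_cat>=20", "bmi_catoverweight", "bmi_catobese",
                   "fpgcv_cat17.6-35.0", "fpgcv_cat>=35.0", "strokeTRUE",
                   "hypertensionTRUE")
  ests <- matrix(0, 5, length(truth_names),
                 dimnames = list(NULL, truth_names))
  for (r in 1:5) {
    spec <- cohort_spec(n_subjects = 30000, seed = 30 + r,
                        covariate_params = list(comorbidity = c(
                          stroke = 0.10, hypertension = 0.361,
                          coronary_artery_disease = 0.15,
                          carotid_atherosclerosis = 0.071,
                          retinopathy = 0.031, hyperlipidemia = 0.217,
                          hyperuricemia = 0.134)))
    d <- suppressWarnings(derive_covariates(generate_cohort(spec)))
    fit <- fit_cox(d, score_terms)
    ests[r, ] <- stats::setNames(fit$beta, fit$terms)[truth_names]
  }
  truth <- stats::setNames(as.numeric(cohort_spec()$true_coefficients),
                           truth_names)
  expect_true(all(abs(colMeans(ests) - truth) < 0.05))
})

test_that("two-stage selection screens, drops collinear pairs, and eliminates backwards", {
  d <- derived_default_cohort(2500, seed = 13)
  # a duplicated candidate is perfectly collinear: flagged, one dropped
  d$stroke_copy <- d$stroke
  sel <- suppressWarnings(select_model(d, c("stroke", "stroke_copy", "age")))
  expect_gte(length(sel$trace$collinearity_flags), 1)
  expect_false(all(c("stroke", "stroke_copy") %in% sel$trace$final_terms))

  # single strongly significant candidate is returned unchanged
  sel2 <- select_model(d, "age")
  expect_equal(sel2$trace$final_terms, "age")
  expect_equal(length(sel2$trace$elimination_steps), 0)

  # invariants of the trace
  expect_true(all(sel2$trace$final_terms %in% sel2$trace$candidates_passing))
  for (s in sel$trace$elimination_steps) expect_gte(s$p, 0.05)
})

test_that("backward elimination keeps a real signal and discards noise", {
  b <- cohort_spec()$true_coefficients * 0
  b["hypertension"] <- 0.5
  keep_strong <- 0; n_null <- integer(0)
  for (r in 1:10) {
    spec <- cohort_spec(n_subjects = 5000, seed = 100 + r,
                        true_coefficients = b,
                        baseline_hazard = list(shape = 1.4, scale = 40))
    d <- suppressWarnings(derive_covariates(generate_cohort(spec)))
    sel <- suppressWarnings(select_model(
      d, c("hypertension", "smoking", "alcohol")))
    keep_strong <- keep_strong + ("hypertension" %in% sel$trace$final_terms)
    n_null <- c(n_null, length(setdiff(sel$trace$final_terms, "hypertension")))
  }
  expect_gte(keep_strong, 9)
  expect_equal(median(n_null), 0)
})

test_that("proportional-hazards diagnostic is calm under PH and alarms under violation", {
  d <- derived_default_cohort(4000, seed = 17)
  fit <- fit_cox(d, c("age", "hypertension"))
  ph <- check_proportional_hazards(fit)
  expect_true(all(ph$p >= 0 & ph$p <= 1))
  expect_equal(ph$term[nrow(ph)], "GLOBAL")

  # strongly time-varying effect: same median, opposite hazard shapes
  flagged <- 0
  for (r in 1:5) {
    set.seed(200 + r)
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    t <- ifelse(x == 1, rweibull(n, shape = 0.5, scale = 5 / log(2)^2),
                rweibull(n, shape = 2.5, scale = 5 / log(2)^0.4))
    dd <- data.frame(follow_up = pmin(t, 12), ckd = as.integer(t <= 12), x = x)
    phx <- check_proportional_hazards(fit_cox(dd, "x"))
    flagged <- flagged + (phx$p[phx$term == "x"] < 0.05)
  }
  expect_gte(flagged, 4)

  # too few events: skipped with a warning
  d6 <- tiny_surv_fixture()
  f6 <- fit_cox(d6, "x")
  expect_warning(out <- check_proportional_hazards(f6), "10 events")
  expect_null(out)
})

test_that("cox fits round-trip through JSON for the score builder", {
  d <- derived_default_cohort()
  fit <- fit_cox(d, c("age", "sex", "stroke"))
  path <- withr::local_tempfile(fileext = ".json")
  write_cox_fit(fit, path)
  back <- read_cox_fit(path)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$terms, fit$terms)
  expect_equal(back$covariate_means, fit$covariate_means, tolerance = 1e-12)
  expect_equal(back$baseline_survival, fit$baseline_survival,
               tolerance = 1e-12)
})
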