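#' Specification of a synthetic type 2 diabetes cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: covariate
#' marginals of a health-screening T2DM population, the true log-hazard
#' ratios of the chronic kidney disease (CKD) event process, a Weibull
#' baseline hazard anchored at the reference covariate profile, and the
#' censoring mechanism (administrative horizon plus geometric annual
#' dropout).
#'
#' The defaults reproduce the study conditions of the derivation cohort the
#' package emulates: mean age 56.44 (SD 10.43) years truncated to 35--78,
#' 76.8% male, BMI 25.38 (SD 3.04) kg/m^2, diabetes-duration categories
#' drawn from the observed category proportions, fasting plasma glucose
#' (FPG) 7.57 (SD 2.46) mmol/L with 2--6 first-year visits and a
#' within-subject dispersion giving a visit-adjusted coefficient of
#' variation around 17%, published comorbidity prevalences, and the
#' published final-model log-hazard ratios as the true coefficients. The
#' Weibull scale and dropout probability are calibrated so that the 10-year
#' cumulative CKD incidence is near 25% and mean follow-up near 8.5 years.
#'
#' @param n_subjects number of subjects (positive integer).
#' @param seed integer seed; the same spec and seed give byte-identical
#'   cohorts.
#' @param covariate_params named list of covariate distribution settings;
#'   see Details. Entries omitted fall back to the defaults.
#' @param true_coefficients named numeric vector of log-hazard ratios for
#'   the terms \code{age} (per year), \code{male}, \code{duration_1_5},
#'   \code{duration_6_10}, \code{duration_11_15}, \code{duration_16_20},
#'   \code{duration_ge20}, \code{bmi_overweight}, \code{bmi_obese},
#'   \code{fpgcv_mid}, \code{fpgcv_high}, \code{stroke},
#'   \code{hypertension}.
#' @param baseline_hazard list with Weibull \code{shape} (> 0, unitless)
#'   and \code{scale} (> 0, years), describing the hazard of the reference
#'   profile (age-band midpoint 37.5 y, female, duration 0, BMI < 24,
#'   FPG-CV < 17.6%, no stroke, no hypertension).
#' @param censoring list with \code{admin_years} (administrative horizon)
#'   and \code{annual_dropout} (per-year dropout probability in [0,1]).
#'
#' @details \code{covariate_params} components:
#' \describe{
#'   \item{age}{list(mean, sd, min, max) in years; truncation bounds must
#'     lie within [35, 78].}
#'   \item{prop_male}{probability of male sex.}
#'   \item{bmi}{list(mean, sd, min, max) in kg/m^2.}
#'   \item{duration_probs}{probabilities of the six diabetes-duration
#'     categories 0, 1--5, 6--10, 11--15, 16--20, >= 20 years.}
#'   \item{comorbidity}{named prevalences for stroke, hypertension,
#'     coronary_artery_disease, carotid_atherosclerosis, retinopathy,
#'     hyperlipidemia, hyperuricemia.}
#'   \item{lifestyle}{named prevalences for smoking, alcohol,
#'     physical_inactivity.}
#'   \item{fpg}{list(mean, sd) of the subject-level FPG mean (mmol/L);
#'     \code{visits_min}/\code{visits_max} bounds of the uniform
#'     first-year visit count; \code{cv_shape}/\code{cv_rate} gamma
#'     parameters of the within-subject log-scale dispersion.}
#'   \item{creatinine}{list(mean, sd) of baseline serum creatinine
#'     (umol/L); re-drawn per subject until baseline eGFR >= 60.}
#'   \item{bmi_hypertension_slope}{log-odds of hypertension per kg/m^2 of
#'     BMI above its mean (marginal prevalence is preserved by intercept
#'     calibration); set 0 for full independence.}
#' }
#'
#' @return an object of class \code{cohort_spec}.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 200, seed = 1)
#' cohort <- generate_cohort(spec)
cohort_spec <- function(n_subjects = 2051,
                        seed = 1,
                        covariate_params = list(),
                        true_coefficients = NULL,
                        baseline_hazard = list(shape = 1.4, scale = 300),
                        censoring = list(admin_years = 10, annual_dropout = 0.005)) {
  defaults <- list(
    age = list(mean = 56.44, sd = 10.43, min = 35, max = 78),
    prop_male = 0.768,
    bmi = list(mean = 25.38, sd = 3.04, min = 16, max = 45),
    duration_probs = c(`0` = 246, `1-5` = 964, `6-10` = 246, `11-15` = 267,
                       `16-20` = 205, `>=20` = 123) / 2051,
    comorbidity = c(stroke = 0.0103, hypertension = 0.361,
                    coronary_artery_disease = 0.150,
                    carotid_atherosclerosis = 0.071, retinopathy = 0.031,
                    hyperlipidemia = 0.217, hyperuricemia = 0.134),
    lifestyle = c(smoking = 0.288, alcohol = 0.113,
                  physical_inactivity = 0.4175),
    fpg = list(mean = 7.57, sd = 2.46, visits_min = 2, visits_max = 6,
               cv_shape = 4.5, cv_rate = 20),
    creatinine = list(mean = 69.16, sd = 13.14),
    bmi_hypertension_slope = 0.15
  )
  cp <- utils::modifyList(defaults, covariate_params)

  if (is.null(true_coefficients)) {
    true_coefficients <- c(
      age = 0.12, male = 0.27,
      duration_1_5 = 0.33, duration_6_10 = 0.48, duration_11_15 = 0.56,
      duration_16_20 = 0.60, duration_ge20 = 1.62,
      bmi_overweight = 0.05, bmi_obese = 0.35,
      fpgcv_mid = 0.08, fpgcv_high = 0.28,
      stroke = 0.51, hypertension = 0.24
    )
  }

  spec <- structure(
    list(n_subjects = n_subjects, seed = seed, covariate_params = cp,
         true_coefficients = true_coefficients,
         baseline_hazard = baseline_hazard, censoring = censoring),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  n <- spec$n_subjects
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n))
    stop_invalid("n_subjects", "must be a positive integer")
  if (!is.numeric(spec$seed) || length(spec$seed) != 1 || is.na(spec$seed))
    stop_invalid("seed", "must be a single integer")
  cp <- spec$covariate_params
  if (cp$age$min < 35 || cp$age$max > 78 || cp$age$min >= cp$age$max)
    stop_invalid("covariate_params$age", "truncation bounds must lie within [35, 78]")
  probs <- c(prop_male = cp$prop_male, cp$comorbidity, cp$lifestyle,
             cp$duration_probs)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop_invalid(paste0("covariate_params (", names(probs)[bad][1], ")"),
                 "probabilities must lie in [0, 1]")
  if (abs(sum(cp$duration_probs) - 1) > 1e-8)
    stop_invalid("covariate_params$duration_probs", "must sum to 1")
  bh <- spec$baseline_hazard
  if (!is.numeric(bh$shape) || bh$shape <= 0)
    stop_invalid("baseline_hazard$shape", "must be > 0")
  if (!is.numeric(bh$scale) || bh$scale <= 0)
    stop_invalid("baseline_hazard$scale", "must be > 0")
  cz <- spec$censoring
  if (!is.numeric(cz$admin_years) || cz$admin_years <= 0)
    stop_invalid("censoring$admin_years", "must be > 0")
  if (cz$annual_dropout < 0 || cz$annual_dropout > 1)
    stop_invalid("censoring$annual_dropout", "must lie in [0, 1]")
  if (cp$fpg$visits_min < 2 || cp$fpg$visits_max < cp$fpg$visits_min)
    stop_invalid("covariate_params$fpg", "visit bounds need visits_min >= 2 and visits_max >= visits_min")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic T2DM cohort specification\n")
  cat(sprintf("  n_subjects: %d, seed: %d\n", x$n_subjects, as.integer(x$seed)))
  cat(sprintf("  baseline hazard: Weibull(shape = %.3g, scale = %.4g y)\n",
              x$baseline_hazard$shape, x$baseline_hazard$scale))
  cat(sprintf("  censoring: administrative %g y, annual dropout %.3g\n",
              x$censoring$admin_years, x$censoring$annual_dropout))
  cat("  true log-hazard ratios:\n")
  print(round(x$true_coefficients, 3))
  invisible(x)
}
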