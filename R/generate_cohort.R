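#' Simulate event times from a Weibull proportional-hazards model
#'
#' Inverse-transform sampling from S(t) = exp(-(t/scale)^shape *
#' exp(linear_predictor)): t = scale * (-log(u) / exp(lp))^(1/shape) with u
#' uniform on (0, 1). When a censoring time is supplied the returned time
#' is truncated at it and the indicator reflects whether the event was
#' observed.
#'
#' @param linear_predictor finite numeric vector (log relative hazard
#'   versus the baseline profile).
#' @param shape,scale Weibull parameters of the baseline hazard (> 0;
#'   scale in years).
#' @param u uniform(0,1) draws; defaults to `runif` of matching length, so
#'   supply it explicitly for reproducible deterministic checks.
#' @param censor_time censoring time(s) in years (default `Inf`).
#' @return data frame with `time` (years) and `event` (1 = event observed,
#'   0 = censored).
#' @export
#' @examples
#' simulate_event_time(0, shape = 1, scale = 1, u = 0.5)  # time = log(2)
simulate_event_time <- function(linear_predictor, shape, scale,
                                u = stats::runif(length(linear_predictor)),
                                censor_time = Inf) {
  if (any(!is.finite(linear_predictor)))
    stop_invalid("linear_predictor", "must be finite")
  if (!is.numeric(shape) || shape <= 0) stop_invalid("shape", "must be > 0")
  if (!is.numeric(scale) || scale <= 0) stop_invalid("scale", "must be > 0")
  t_event <- scale * (-log(u) / exp(linear_predictor))^(1 / shape)
  time <- pmin(t_event, censor_time)
  data.frame(time = time, event = as.integer(t_event <= censor_time))
}

#' Generate a synthetic T2DM cohort
#'
#' Draws `n_subjects` subject records from a [cohort_spec()]: baseline
#' covariates from the specified marginals (with a configurable positive
#' BMI--hypertension association), a first-year fasting plasma glucose
#' series per subject (lognormal around a subject-level mean, 2--6
#' visits), baseline serum creatinine constrained so that nobody has CKD
#' at entry, and a time to incident CKD from a Weibull
#' proportional-hazards model whose linear predictor uses the spec's
#' `true_coefficients` on the derived score covariates (age in years,
#' male, duration / BMI / FPG-CV categories, stroke, hypertension).
#' Censoring is the minimum of geometric annual dropout and the
#' administrative horizon.
#'
#' @param spec a [cohort_spec()].
#' @return data frame, one row per subject, with columns `subject_id`,
#'   `age`, `sex`, `bmi`, `diabetes_duration`, `smoking`, `alcohol`,
#'   `physical_inactivity`, comorbidity flags (`stroke`, `hypertension`,
#'   `coronary_artery_disease`, `carotid_atherosclerosis`, `retinopathy`,
#'   `hyperlipidemia`, `hyperuricemia`), `serum_creatinine` (umol/L),
#'   `proteinuria_dipstick`, `fpg_series` (semicolon-delimited
#'   "day:value" pairs, days from index), `event_time` (years) and
#'   `event_indicator` ("CKD" or "censored").
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_subjects
  cp <- spec$covariate_params
  b <- spec$true_coefficients

  age <- rnorm_trunc(n, cp$age$mean, cp$age$sd, cp$age$min, cp$age$max)
  sex <- ifelse(stats::runif(n) < cp$prop_male, "male", "female")
  bmi <- rnorm_trunc(n, cp$bmi$mean, cp$bmi$sd, cp$bmi$min, cp$bmi$max)

  dur_cat <- sample(names(cp$duration_probs), n, replace = TRUE,
                    prob = cp$duration_probs)
  duration <- duration_within_band(dur_cat)

  com <- cp$comorbidity
  flags <- lapply(com[setdiff(names(com), "hypertension")],
                  function(p) stats::runif(n) < p)
  # hypertension: logistic in BMI, intercept calibrated to keep the marginal
  slope <- cp$bmi_hypertension_slope
  eta <- slope * (bmi - mean(bmi))
  a0 <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - com[["hypertension"]],
                       c(-20, 20))$root
  hypertension <- stats::runif(n) < stats::plogis(a0 + eta)

  life <- lapply(cp$lifestyle, function(p) stats::runif(n) < p)

  # first-year FPG series: subject mean lognormal matched to the cohort
  # mean/SD, within-subject lognormal dispersion drawn per subject
  cvg <- cp$fpg$sd / cp$fpg$mean
  sdlog_m <- sqrt(log(1 + cvg^2))
  meanlog_m <- log(cp$fpg$mean) - sdlog_m^2 / 2
  fpg_m <- stats::rlnorm(n, meanlog_m, sdlog_m)
  sigma <- stats::rgamma(n, shape = cp$fpg$cv_shape, rate = cp$fpg$cv_rate)
  n_visits <- sample(cp$fpg$visits_min:cp$fpg$visits_max, n, replace = TRUE)
  days <- lapply(n_visits, function(k) sort(sample(0:365, k)))
  values <- mapply(function(m, s, k) m * exp(stats::rnorm(k, 0, s) - s^2 / 2),
                   fpg_m, sigma, n_visits, SIMPLIFY = FALSE)
  fpg_cv <- vapply(values, compute_fpg_cv, numeric(1))

  scr <- draw_creatinine(n, cp$creatinine, age, sex)

  dcat <- factor(dur_cat, levels = c("0", "1-5", "6-10", "11-15", "16-20", ">=20"))
  bcat <- bmi_category(bmi)
  fcat <- fpgcv_category(fpg_cv)
  lp <- b[["age"]] * (age - 37.5) +
    b[["male"]] * (sex == "male") +
    b[["duration_1_5"]] * (dcat == "1-5") +
    b[["duration_6_10"]] * (dcat == "6-10") +
    b[["duration_11_15"]] * (dcat == "11-15") +
    b[["duration_16_20"]] * (dcat == "16-20") +
    b[["duration_ge20"]] * (dcat == ">=20") +
    b[["bmi_overweight"]] * (bcat == "overweight") +
    b[["bmi_obese"]] * (bcat == "obese") +
    b[["fpgcv_mid"]] * (fcat == "17.6-35.0") +
    b[["fpgcv_high"]] * (fcat == ">=35.0") +
    b[["stroke"]] * flags$stroke +
    b[["hypertension"]] * hypertension

  q <- spec$censoring$annual_dropout
  dropout <- if (q > 0) stats::rgeom(n, q) + stats::runif(n) else rep(Inf, n)
  censor <- pmin(dropout, spec$censoring$admin_years)
  ev <- simulate_event_time(lp, spec$baseline_hazard$shape,
                            spec$baseline_hazard$scale, censor_time = censor)

  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = age, sex = sex, bmi = bmi, diabetes_duration = duration,
    smoking = life$smoking, alcohol = life$alcohol,
    physical_inactivity = life$physical_inactivity,
    stroke = flags$stroke, hypertension = hypertension,
    coronary_artery_disease = flags$coronary_artery_disease,
    carotid_atherosclerosis = flags$carotid_atherosclerosis,
    retinopathy = flags$retinopathy, hyperlipidemia = flags$hyperlipidemia,
    hyperuricemia = flags$hyperuricemia,
    serum_creatinine = scr,
    proteinuria_dipstick = "negative",
    fpg_series = format_fpg_series(days, values),
    event_time = ev$time,
    event_indicator = ifelse(ev$event == 1, "CKD", "censored"),
    stringsAsFactors = FALSE
  )
}

# integer duration within each published category
duration_within_band <- function(dur_cat) {
  n <- length(dur_cat)
  duration <- numeric(n)
  pick <- function(lo, hi, k) if (k) sample(lo:hi, k, replace = TRUE) else integer(0)
  for (band in list(c("1-5", 1, 5), c("6-10", 6, 10), c("11-15", 11, 15),
                    c("16-20", 16, 19))) {
    i <- dur_cat == band[1]
    duration[i] <- pick(as.integer(band[2]), as.integer(band[3]), sum(i))
  }
  i <- dur_cat == ">=20"
  duration[i] <- pmin(20 + stats::rgeom(sum(i), 0.3), 35)
  duration
}

# baseline creatinine with no baseline CKD: redraw until eGFR >= 60
draw_creatinine <- function(n, pars, age, sex) {
  scr <- rnorm_trunc(n, pars$mean, pars$sd, 40, 140)
  for (it in 1:25) {
    low <- compute_egfr(scr, age, sex) < 60
    if (!any(low)) break
    scr[low] <- rnorm_trunc(sum(low), pars$mean, pars$sd, 40, 140)
  }
  low <- compute_egfr(scr, age, sex) < 60
  if (any(low)) {
    # solve the eGFR formula for the creatinine giving eGFR = 62
    fem <- ifelse(sex[low] == "female", 0.79, 1)
    scr[low] <- 88.4 * (175 * fem * age[low]^-0.287 / 62)^(1 / 1.234)
  }
  scr
}

#' Read and write cohort tables
#'
#' Cohorts are stored as tab-delimited text, one row per subject, with the
#' FPG series as a semicolon-delimited "day:value" sub-field.
#' `write_cohort` also writes a JSON sidecar (`<path>.spec.json`) echoing
#' the generating [cohort_spec()] when one is supplied.
#'
#' @param cohort cohort data frame ([generate_cohort()] schema).
#' @param path file path of the tab-delimited table.
#' @param spec optional [cohort_spec()] echoed to the JSON sidecar.
#' @return `read_cohort` returns the cohort data frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path, spec = NULL) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
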