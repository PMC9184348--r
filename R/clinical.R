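#' Estimated glomerular filtration rate (modified MDRD equation for
#' Chinese adults)
#'
#' eGFR (mL/min/1.73 m^2) = 175 x Scr^-1.234 x age^-0.287 (x 0.79 if
#' female), with serum creatinine entered in mg/dL. Creatinine is supplied
#' in umol/L (as reported by enzymatic assays) and converted internally by
#' dividing by 88.4.
#'
#' @param scr serum creatinine, umol/L (> 0).
#' @param age age in years (> 0).
#' @param sex character vector, "male" or "female".
#' @return eGFR in mL/min/1.73 m^2; strictly decreasing in both `scr` and
#'   `age`.
#' @export
#' @examples
#' compute_egfr(88.4, 50, "male")   # creatinine 1.0 mg/dL
compute_egfr <- function(scr, age, sex) {
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop_invalid("scr", "serum creatinine must be finite and > 0")
  if (any(!is.finite(age)) || any(age <= 0))
    stop_invalid("age", "age must be finite and > 0")
  sex <- match_sex(sex)
  scr_mgdl <- scr / 88.4
  egfr <- 175 * scr_mgdl^-1.234 * age^-0.287
  egfr * ifelse(sex == "female", 0.79, 1)
}

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female")))
    stop_invalid("sex", "must be 'male' or 'female'")
  sex
}

#' Dipstick proteinuria grades
#'
#' Ordered grades of the urine dipstick protein test; a result of 1+ or
#' higher counts as positive proteinuria.
#' @export
dipstick_levels <- function() c("negative", "trace", "1+", "2+", "3+", "4+")

#' Classify chronic kidney disease status
#'
#' CKD is present when eGFR < 60 mL/min/1.73 m^2 and/or dipstick
#' proteinuria is positive (>= 1+).
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (>= 0).
#' @param dipstick dipstick grade, one of [dipstick_levels()].
#' @return logical vector; monotone in both arguments (lower eGFR or a
#'   higher grade never turns TRUE into FALSE).
#' @export
classify_ckd <- function(egfr, dipstick) {
  if (any(!is.finite(egfr)) || any(egfr < 0))
    stop_invalid("egfr", "must be finite and >= 0")
  lev <- dipstick_levels()
  dipstick <- as.character(dipstick)
  if (!all(dipstick %in% lev))
    stop_invalid("dipstick", paste("grades must be one of:", paste(lev, collapse = ", ")))
  grade <- match(dipstick, lev) - 1L        # 0 = negative ... 5 = 4+
  egfr < 60 | grade >= 2L
}

#' Visit-adjusted coefficient of variation of fasting plasma glucose
#'
#' The raw CV is the sample SD (n - 1 denominator) over the mean of all
#' first-year FPG measurements; it is then divided by sqrt(n / (n - 1))
#' (equivalently multiplied by sqrt((n - 1) / n)) to adjust for the number
#' of visits, and reported as a percentage.
#'
#' @param values numeric vector of >= 2 FPG measurements (mmol/L, > 0).
#' @return adjusted CV in percent; invariant to rescaling all values by a
#'   positive constant.
#' @export
#' @examples
#' compute_fpg_cv(c(6, 8))   # raw 20.20%, adjusted 14.29%
compute_fpg_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop_invalid("values", "at least two first-year FPG measurements are required")
  if (any(!is.finite(values)) || any(values <= 0))
    stop_invalid("values", "FPG measurements must be finite and > 0")
  n <- length(values)
  100 * (stats::sd(values) / mean(values)) * sqrt((n - 1) / n)
}

#' Category assignment for score covariates
#'
#' Band conventions follow the published strata: bands are closed on the
#' left and open on the right, except the terminal ">=" band which is
#' closed. BMI below 18.5 kg/m^2 is assigned "normal" with a warning (no
#' underweight band is defined).
#'
#' @param bmi body mass index, kg/m^2.
#' @return factor with levels `normal` (< 24), `overweight` (24--27.9),
#'   `obese` (>= 28).
#' @export
#' @rdname categorize
bmi_category <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop_invalid("bmi", "must be finite and > 0")
  if (any(bmi < 18.5))
    warning(sprintf("%d BMI value(s) below 18.5 kg/m^2 assigned to 'normal' (no underweight band)",
                    sum(bmi < 18.5)))
  cut(bmi, breaks = c(-Inf, 24, 28, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"))
}

#' @param duration diabetes duration, years (>= 0).
#' @return factor with levels `0`, `1-5`, `6-10`, `11-15`, `16-20`, `>=20`.
#' @export
#' @rdname categorize
duration_category <- function(duration) {
  if (any(!is.finite(duration)) || any(duration < 0))
    stop_invalid("duration", "must be finite and >= 0")
  cut(duration, breaks = c(0, 1, 6, 11, 16, 20, Inf), right = FALSE,
      labels = c("0", "1-5", "6-10", "11-15", "16-20", ">=20"))
}

#' @param fpg_cv adjusted FPG coefficient of variation, percent.
#' @return factor with levels `<17.6`, `17.6-35.0`, `>=35.0` (tertile-based
#'   cut points of the derivation cohort).
#' @export
#' @rdname categorize
fpgcv_category <- function(fpg_cv) {
  if (any(!is.finite(fpg_cv)) || any(fpg_cv < 0))
    stop_invalid("fpg_cv", "must be finite and >= 0")
  cut(fpg_cv, breaks = c(-Inf, 17.6, 35, Inf), right = FALSE,
      labels = c("<17.6", "17.6-35.0", ">=35.0"))
}

#' @param age age in years.
#' @return integer 5-year age-band index: floor((age - 35)/5) clipped to
#'   [0, 8] (band 0 = 35--39, band 8 = 75--79).
#' @export
#' @rdname categorize
age_band <- function(age) {
  if (any(!is.finite(age)) || any(age <= 0))
    stop_invalid("age", "must be finite and > 0")
  pmin(pmax(floor((age - 35) / 5), 0), 8)
}

#' Midpoint dating of CKD onset
#'
#' The onset date is the midpoint (floor convention) between the last
#' CKD-free visit and the first visit at which CKD was diagnosed.
#'
#' @param last_ckd_free,first_ckd visit days from the index date (integers
#'   or Date); `first_ckd` must be strictly later.
#' @return days from index (or Date), `last_ckd_free + floor(delta / 2)`.
#' @export
onset_midpoint <- function(last_ckd_free, first_ckd) {
  delta <- as.numeric(first_ckd) - as.numeric(last_ckd_free)
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop_invalid("first_ckd", "must be strictly later than last_ckd_free")
  last_ckd_free + floor(delta / 2)
}

#' Incidence rate per 1000 person-years
#'
#' @param cases number of incident cases (>= 0).
#' @param person_years total person-years at risk (> 0).
#' @return cases / person_years x 1000.
#' @export
#' @examples
#' incidence_rate(504, 17479)   # 28.83 per 1000 person-years
incidence_rate <- function(cases, person_years) {
  if (any(!is.finite(cases)) || any(cases < 0))
    stop_invalid("cases", "must be finite and >= 0")
  if (any(!is.finite(person_years)) || any(person_years <= 0))
    stop_invalid("person_years", "must be finite and > 0")
  cases / person_years * 1000
}

#' Derive clinical covariates for a cohort
#'
#' Augments a cohort table with every derived quantity the modeling stages
#' use: first-year FPG summary (visit count, mean, SD, visit-adjusted CV in
#' percent), baseline eGFR and CKD status, category assignments (BMI,
#' diabetes duration, FPG-CV, 5-year age band) and follow-up in years.
#'
#' @param cohort a data frame in the cohort schema of [generate_cohort()] /
#'   [read_cohort()].
#' @return the cohort with derived columns `fpg_n`, `fpg_mean`, `fpg_sd`,
#'   `fpg_cv`, `egfr`, `ckd_baseline`, `bmi_cat`, `duration_cat`,
#'   `fpgcv_cat`, `age_band`, `follow_up`, `ckd` appended.
#' @export
derive_covariates <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  series <- parse_fpg_series(cohort$fpg_series)
  vals <- lapply(series, function(s) s$fpg)
  n_visits <- vapply(vals, length, integer(1))
  if (any(n_visits < 2))
    stop_invalid("fpg_series", "every subject needs >= 2 first-year FPG measurements")
  cohort$fpg_n <- n_visits
  cohort$fpg_mean <- vapply(vals, mean, numeric(1))
  cohort$fpg_sd <- vapply(vals, stats::sd, numeric(1))
  cohort$fpg_cv <- vapply(vals, compute_fpg_cv, numeric(1))
  cohort$egfr <- compute_egfr(cohort$serum_creatinine, cohort$age, cohort$sex)
  cohort$ckd_baseline <- classify_ckd(cohort$egfr, cohort$proteinuria_dipstick)
  cohort$bmi_cat <- bmi_category(cohort$bmi)
  cohort$duration_cat <- duration_category(cohort$diabetes_duration)
  cohort$fpgcv_cat <- fpgcv_category(cohort$fpg_cv)
  cohort$age_band <- age_band(cohort$age)
  cohort$follow_up <- cohort$event_time
  cohort$ckd <- as.integer(cohort$event_indicator == "CKD")
  cohort
}

#' Stratified incidence summary
#'
#' Per-stratum subject counts, incident cases, person-years and incidence
#' rates per 1000 person-years, for one or more stratifying factors of a
#' derived cohort.
#'
#' @param derived a derived cohort from [derive_covariates()].
#' @param factors character vector of column names to stratify by.
#' @return data frame with columns `factor`, `stratum`, `n`, `cases`,
#'   `person_years`, `rate`.
#' @export
incidence_table <- function(derived, factors) {
  stopifnot(all(factors %in% names(derived)))
  out <- lapply(factors, function(f) {
    g <- derived[[f]]
    if (is.logical(g)) g <- factor(g, c(FALSE, TRUE), c("No", "Yes"))
    g <- as.factor(g)
    agg <- lapply(split(derived, g), function(d)
      c(n = nrow(d), cases = sum(d$ckd), person_years = sum(d$follow_up)))
    m <- do.call(rbind, agg)
    data.frame(factor = f, stratum = rownames(m), n = m[, "n"],
               cases = m[, "cases"], person_years = m[, "person_years"],
               rate = incidence_rate(m[, "cases"], m[, "person_years"]),
               row.names = NULL)
  })
  do.call(rbind, out)
}

# "day:value;day:value" <-> list(data.frame(day, fpg))
parse_fpg_series <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(parts) {
    m <- do.call(rbind, strsplit(parts, ":", fixed = TRUE))
    data.frame(day = as.numeric(m[, 1]), fpg = as.numeric(m[, 2]))
  })
}

format_fpg_series <- function(days, values) {
  mapply(function(d, v) paste(sprintf("%d:%.6g", d, v), collapse = ";"),
         days, values)
}
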