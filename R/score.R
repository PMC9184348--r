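#' Regression units per point (the constant B)
#'
#' In the Framingham/Sullivan points system one point represents the
#' hazard increment associated with 5 years of age, so B = 5 x beta_age
#' with age entered per year in the Cox model.
#'
#' @param fit a `cox_fit` containing an `age` term (per year).
#' @param age_term name of the age term in the fit.
#' @return the constant B (> 0, regression units per point).
#' @export
#' @examples
#' # beta_age = 0.12 per year -> B = 0.60
compute_constant_B <- function(fit, age_term = "age") {
  idx <- match(age_term, fit$terms)
  if (is.na(idx))
    stop_invalid("fit", sprintf("no '%s' term present", age_term))
  beta_age <- fit$beta[idx]
  if (beta_age <= 0)
    stop_invalid("fit", "age coefficient must be positive (score direction undefined)")
  5 * beta_age
}

#' Integer points for a risk-factor category
#'
#' Point_ij = beta_i x (W_ij - W_iREF) / B, rounded half-up to the nearest
#' integer and floored at 0. For indicator categories W_ij - W_iREF = 1,
#' so the points are round(beta_i / B).
#'
#' @param beta log-hazard ratio of the factor.
#' @param w reference value W_ij of the category (e.g. the age-band
#'   midpoint offset in years, or 1 for an indicator).
#' @param w_ref reference value W_iREF of the base category (default 0).
#' @param constant_B regression units per point (> 0).
#' @return non-negative integer points.
#' @export
#' @examples
#' assign_points(0.51, constant_B = 0.60)   # stroke: 0.85 -> 1 point
assign_points <- function(beta, w = 1, w_ref = 0, constant_B) {
  if (!is.numeric(constant_B) || constant_B <= 0)
    stop_invalid("constant_B", "must be > 0")
  pmax(round_half_up(beta * (w - w_ref) / constant_B), 0L)
}

# category grids shared by the sheet builders; `column` names the derived
# cohort column holding each factor's category
score_factor_grid <- function() {
  list(
    age = list(column = "age_band",
               categories = c("35-39", "40-44", "45-49", "50-54", "55-59",
                              "60-64", "65-69", "70-74", "75-78"),
               w = 5 * (0:8)),
    sex = list(column = "sex", categories = c("female", "male"), w = c(0, 1)),
    duration = list(column = "duration_cat",
                    categories = c("0", "1-5", "6-10", "11-15", "16-20", ">=20"),
                    w = c(0, 1, 1, 1, 1, 1), multi_beta = TRUE),
    bmi = list(column = "bmi_cat",
               categories = c("normal", "overweight", "obese"),
               w = c(0, 1, 1), multi_beta = TRUE),
    fpg_cv = list(column = "fpgcv_cat",
                  categories = c("<17.6", "17.6-35.0", ">=35.0"),
                  w = c(0, 1, 1), multi_beta = TRUE),
    stroke = list(column = "stroke", categories = c("FALSE", "TRUE"), w = c(0, 1)),
    hypertension = list(column = "hypertension", categories = c("FALSE", "TRUE"),
                        w = c(0, 1))
  )
}

new_score_sheet <- function(factors, constant_B) {
  stopifnot(is.data.frame(factors),
            all(c("factor", "category", "w", "w_ref", "beta", "points") %in%
                  names(factors)))
  if (any(factors$points < 0) || any(factors$points != floor(factors$points)))
    stop_invalid("factors", "points must be non-negative integers")
  base0 <- tapply(factors$points, factors$factor, function(p) p[1] == 0)
  if (!all(base0))
    stop_invalid("factors", "the base category of every factor must score 0")
  structure(list(
    constant_B = constant_B,
    factors = factors,
    min_total = 0L,
    max_total = as.integer(sum(tapply(factors$points, factors$factor, max)))
  ), class = "score_sheet")
}

#' Build an integer score sheet from a fitted Cox model
#'
#' Implements the Framingham/Sullivan construction: risk factors are
#' categorized (5-year age bands from 35, sex, diabetes-duration bands,
#' BMI bands, FPG-CV tertile bands, stroke, hypertension); each category
#' receives a reference value W_ij (age: band-midpoint offset in years;
#' others: indicator 0/1) against a base profile with score 0; the
#' distance from base in regression units, beta_i x (W_ij - W_iREF), is
#' divided by the constant B = 5 x beta_age and rounded to integer points.
#' Raw (unrounded) quotients are retained in the sheet for audit.
#'
#' @param fit a `cox_fit` whose terms follow the derived-cohort naming
#'   (`age`, `sexmale`, `duration_cat*`, `bmi_cat*`, `fpgcv_cat*`,
#'   `strokeTRUE`, `hypertensionTRUE`); terms absent from the fit
#'   contribute no points.
#' @param constant_B regression units per point; defaults to
#'   [compute_constant_B()] of the fit.
#' @return a `score_sheet`: `constant_B`, `factors` (factor, category, w,
#'   w_ref, beta, quotient, points), `min_total`, `max_total`.
#' @export
build_score_sheet <- function(fit, constant_B = compute_constant_B(fit)) {
  grid <- score_factor_grid()
  beta_of <- function(term) {
    i <- match(term, fit$terms)
    if (is.na(i)) 0 else fit$beta[i]
  }
  term_map <- list(
    age = function(cat) "age",
    sex = function(cat) "sexmale",
    duration = function(cat) paste0("duration_cat", cat),
    bmi = function(cat) paste0("bmi_cat", cat),
    fpg_cv = function(cat) paste0("fpgcv_cat", cat),
    stroke = function(cat) "strokeTRUE",
    hypertension = function(cat) "hypertensionTRUE"
  )
  rows <- lapply(names(grid), function(f) {
    g <- grid[[f]]
    beta <- vapply(g$categories, function(cat) beta_of(term_map[[f]](cat)),
                   numeric(1))
    quotient <- beta * (g$w - g$w[1]) / constant_B
    data.frame(factor = f, category = g$categories, w = g$w, w_ref = g$w[1],
               beta = unname(beta), quotient = unname(quotient),
               points = assign_points(beta, g$w, g$w[1], constant_B),
               row.names = NULL)
  })
  new_score_sheet(do.call(rbind, rows), constant_B)
}

#' The published CKD score sheet
#'
#' The reference score sheet of the published derivation cohort of Chinese
#' health-screening examinees with type 2 diabetes: the final-model
#' log-hazard ratios (with standard errors and cohort means/proportions)
#' and the published integer points. The published points are carried
#' verbatim; note that for some categories (male, hypertension, FPG-CV
#' >= 35%, duration >= 20 y) they differ from what rounding
#' beta x (W - W_ref)/B gives under any single rounding rule, so this
#' sheet is the authority for the published total-score range 0--15 while
#' [build_score_sheet()] is the reproducible construction.
#'
#' @return a `score_sheet` with additional per-category columns `se` and
#'   `mean` (published mean or proportion).
#' @export
published_score_sheet <- function() {
  grid <- score_factor_grid()
  B <- 5 * 0.12
  rows <- list(
    data.frame(factor = "age", category = grid$age$categories,
               w = grid$age$w, w_ref = 0, beta = 0.12, se = 0.07,
               mean = 56.44, points = 0:8),
    data.frame(factor = "sex", category = c("female", "male"), w = c(0, 1),
               w_ref = 0, beta = c(0, 0.27), se = c(NA, 0.12),
               mean = c(NA, 0.24), points = c(0L, 1L)),
    data.frame(factor = "duration",
               category = c("0", "1-5", "6-10", "11-15", "16-20", ">=20"),
               w = c(0, 1, 1, 1, 1, 1), w_ref = 0,
               beta = c(0, 0.33, 0.48, 0.56, 0.60, 1.62),
               se = c(NA, 0.07, 0.15, 0.17, 0.20, 0.46),
               mean = c(NA, 0.47, 0.12, 0.13, 0.10, 0.06),
               points = c(0L, 1L, 1L, 1L, 1L, 2L)),
    data.frame(factor = "bmi", category = c("normal", "overweight", "obese"),
               w = c(0, 1, 1), w_ref = 0, beta = c(0, 0.05, 0.35),
               se = c(NA, 0.11, 0.09), mean = c(NA, 0.55, 0.14),
               points = c(0L, 0L, 1L)),
    data.frame(factor = "fpg_cv", category = c("<17.6", "17.6-35.0", ">=35.0"),
               w = c(0, 1, 1), w_ref = 0, beta = c(0, 0.08, 0.28),
               se = c(NA, 0.12, 0.05), mean = c(NA, 0.34, 0.08),
               points = c(0L, 0L, 1L)),
    data.frame(factor = "stroke", category = c("FALSE", "TRUE"), w = c(0, 1),
               w_ref = 0, beta = c(0, 0.51), se = c(NA, 0.15),
               mean = c(NA, 0.01), points = c(0L, 1L)),
    data.frame(factor = "hypertension", category = c("FALSE", "TRUE"),
               w = c(0, 1), w_ref = 0, beta = c(0, 0.24), se = c(NA, 0.05),
               mean = c(NA, 0.36), points = c(0L, 1L))
  )
  factors <- do.call(rbind, rows)
  factors$quotient <- factors$beta * (factors$w - factors$w_ref) / B
  new_score_sheet(factors, B)
}

#' Published stratified incidence counts
#'
#' Incident CKD cases and person-years of the published cohort, by
#' baseline predictor stratum; inputs for recomputing the published
#' incidence rates per 1000 person-years with [incidence_rate()].
#'
#' @return data frame with `factor`, `stratum`, `n`, `cases`,
#'   `person_years`.
#' @export
published_incidence_counts <- function() {
  data.frame(
    factor = c("overall", "sex", "sex",
               rep("duration", 6), rep("bmi", 3), rep("fpg_cv", 3),
               rep("stroke", 2), rep("hypertension", 2)),
    stratum = c("all", "female", "male",
                "0", "1-5", "6-10", "11-15", "16-20", ">=20",
                "<24", "24-28", ">=28", "<17.6", "17.6-35.0", ">=35.0",
                "no", "yes", "no", "yes"),
    n = c(2051, 469, 1582, 246, 964, 246, 267, 205, 123,
          637, 1120, 294, 1183, 707, 161, 2030, 21, 1309, 742),
    cases = c(504, 77, 427, 22, 202, 62, 82, 66, 70,
              102, 255, 147, 238, 203, 63, 490, 14, 294, 210),
    person_years = c(17479, 4158, 13321, 2096, 8213, 2096, 2275, 1747, 1048,
                     5427, 9542, 2505, 10079, 6024, 1372, 17296, 179,
                     11153, 6322)
  )
}

#' @export
print.score_sheet <- function(x, ...) {
  cat(sprintf("CKD risk score sheet (B = %.3g regression units per point)\n",
              x$constant_B))
  f <- x$factors
  f$beta <- round(f$beta, 3)
  if (!is.null(f$quotient)) f$quotient <- round(f$quotient, 3)
  print(f, row.names = FALSE)
  cat(sprintf("Total score range: %d-%d\n", x$min_total, x$max_total))
  invisible(x)
}

#' Total score for subject category profiles
#'
#' @param categories named list or data frame giving each sheet factor's
#'   category per subject (names must cover every factor of the sheet;
#'   logical flags may be given as logicals).
#' @param sheet a `score_sheet`.
#' @return integer total(s) in `[sheet$min_total, sheet$max_total]`.
#' @export
#' @examples
#' sheet <- published_score_sheet()
#' total_points(list(age = "75-78", sex = "male", duration = ">=20",
#'                   bmi = "obese", fpg_cv = ">=35.0", stroke = TRUE,
#'                   hypertension = TRUE), sheet)   # 15
total_points <- function(categories, sheet) {
  stopifnot(inherits(sheet, "score_sheet"))
  fs <- unique(sheet$factors$factor)
  missing_f <- setdiff(fs, names(categories))
  if (length(missing_f))
    stop_invalid("categories", paste("missing factor(s):",
                                     paste(missing_f, collapse = ", ")))
  nsub <- max(vapply(categories[fs], length, integer(1)))
  total <- integer(nsub)
  for (f in fs) {
    rows <- sheet$factors[sheet$factors$factor == f, ]
    cat_f <- as.character(categories[[f]])
    i <- match(cat_f, rows$category)
    if (anyNA(i))
      stop_invalid("categories",
                   sprintf("unknown category '%s' for factor '%s'",
                           cat_f[which(is.na(i))[1]], f))
    total <- total + rows$points[i]
  }
  as.integer(total)
}

#' Score every subject of a derived cohort
#'
#' Maps the derived covariate columns onto the sheet's category grid and
#' sums the points.
#'
#' @param derived a derived cohort ([derive_covariates()]).
#' @param sheet a `score_sheet`.
#' @return integer vector of total points, one per subject.
#' @export
score_subjects <- function(derived, sheet) {
  grid <- score_factor_grid()
  cats <- list(
    age = grid$age$categories[derived$age_band + 1],
    sex = as.character(derived$sex),
    duration = as.character(derived$duration_cat),
    bmi = as.character(derived$bmi_cat),
    fpg_cv = as.character(derived$fpgcv_cat),
    stroke = as.character(derived$stroke),
    hypertension = as.character(derived$hypertension)
  )
  total_points(cats, sheet)
}

#' Predicted CKD risk for every possible point total
#'
#' Maps each total P to an absolute risk through the survival-model
#' equation risk(t) = 1 - S0(t)^exp(u(P)), with S0(t) the Breslow
#' baseline survival at the mean covariate profile and u(P) the distance
#' of the point total's linear predictor from the cohort mean
#' LP_mean = sum of beta_i x mean_i. Two anchoring conventions are
#' offered:
#' \describe{
#'   \item{mean}{(default) u(P) = B x (P - mean_points), where
#'     `mean_points` is the mean point total of the derivation cohort.
#'     A subject at the cohort-mean score receives the mean-profile risk,
#'     so the integer rounding of category points does not shift the
#'     average predicted risk.}
#'   \item{base}{u(P) = LP_base + B x P - LP_mean, where LP_base is the
#'     linear predictor of the all-base-category profile (age at the
#'     reference band midpoint 37.5 y, female, duration 0, BMI < 24,
#'     FPG-CV < 17.6%, no stroke, no hypertension). Categories whose
#'     points round to 0 then contribute nothing, which systematically
#'     lowers the predicted risks when several do.}
#' }
#' Risks are clipped to [0, 1].
#'
#' @param sheet a `score_sheet`.
#' @param fit the `cox_fit` providing baseline survival and covariate
#'   means.
#' @param horizons years; defaults to the fit's horizons.
#' @param anchor "mean" or "base"; see Description.
#' @param mean_points mean point total of the derivation cohort (e.g.
#'   `mean(score_subjects(derived, sheet))`); required for the mean
#'   anchor.
#' @return a `risk_table` data frame: `point_total` (0..max_total) and one
#'   `risk_<t>y` column per horizon; risks are non-decreasing in both the
#'   point total and the horizon.
#' @export
build_risk_table <- function(sheet, fit, horizons = fit$horizons,
                             anchor = c("mean", "base"),
                             mean_points = NULL) {
  stopifnot(inherits(sheet, "score_sheet"), inherits(fit, "cox_fit"))
  anchor <- match.arg(anchor)
  s0 <- fit$baseline_survival[match(horizons, fit$horizons)]
  if (anyNA(s0))
    stop_invalid("horizons", "baseline survival not available at a requested horizon")
  if (any(s0 <= 0) || any(s0 > 1))
    stop_invalid("fit", "baseline survival must lie in (0, 1]")
  totals <- sheet$min_total:sheet$max_total
  if (anchor == "mean") {
    if (is.null(mean_points))
      stop_invalid("mean_points", "required for the mean anchor")
    u <- sheet$constant_B * (totals - mean_points)
  } else {
    lp_mean <- sum(fit$beta * fit$covariate_means)
    age_idx <- match("age", fit$terms)
    lp_base <- if (is.na(age_idx)) 0 else fit$beta[age_idx] * 37.5
    u <- lp_base + sheet$constant_B * totals - lp_mean
  }
  out <- data.frame(point_total = totals)
  for (k in seq_along(horizons)) {
    risk <- 1 - s0[k]^exp(u)
    out[[sprintf("risk_%gy", horizons[k])]] <- pmin(pmax(risk, 0), 1)
  }
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Look up predicted risks for point totals
#'
#' @param risk_table a `risk_table` from [build_risk_table()].
#' @param points integer point totals.
#' @param horizon horizon in years (a `risk_<horizon>y` column must
#'   exist).
#' @return numeric predicted risks.
#' @export
predict_risk <- function(risk_table, points, horizon) {
  col <- sprintf("risk_%gy", horizon)
  if (!col %in% names(risk_table))
    stop_invalid("horizon", sprintf("no column '%s' in the risk table", col))
  i <- match(points, risk_table$point_total)
  if (anyNA(i))
    stop_invalid("points", "point total outside the table range")
  risk_table[[col]][i]
}

#' Serialize a score sheet (JSON) and risk table (TSV)
#' @param sheet a `score_sheet`.
#' @param path output file path.
#' @export
write_score_sheet <- function(sheet, path) {
  jsonlite::write_json(list(constant_B = sheet$constant_B,
                            min_total = sheet$min_total,
                            max_total = sheet$max_total,
                            factors = sheet$factors),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_sheet
#' @export
read_score_sheet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$factors$points <- as.integer(x$factors$points)
  new_score_sheet(x$factors, x$constant_B)
}

#' @rdname write_score_sheet
#' @param risk_table a `risk_table`.
#' @export
write_risk_table <- function(risk_table, path) {
  utils::write.table(as.data.frame(risk_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_sheet
#' @export
read_risk_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE)
  class(out) <- c("risk_table", "data.frame")
  out
}
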