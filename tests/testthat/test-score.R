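test_that("the constant B is five times the per-year age coefficient", {
  f <- fake_cox_fit(c("age", "strokeTRUE"), c(0.12, 0.51))
  expect_equal(compute_constant_B(f), 0.60)
  f2 <- fake_cox_fit("age", 0.20)
  expect_equal(compute_constant_B(f2), 1.00)
  expect_error(compute_constant_B(fake_cox_fit("age", -0.1)), "positive")
  expect_error(compute_constant_B(fake_cox_fit("x", 0.2)), "age")
})

test_that("point assignment rounds half-up, floors at zero, and spans age bands", {
  expect_equal(assign_points(0.51, constant_B = 0.60), 1)   # stroke
  expect_equal(assign_points(0, constant_B = 0.60), 0)
  expect_equal(assign_points(-0.4, constant_B = 0.60), 0)   # floored
  # age band k at beta 0.12/year, W = 5k years: exactly k points
  expect_equal(assign_points(0.12, w = 5 * (0:8), w_ref = 0,
                             constant_B = 0.60), 0:8)
  # round-half-up at the boundary: 0.30/0.60 = 0.5 -> 1
  expect_equal(assign_points(0.30, constant_B = 0.60), 1)
  expect_error(assign_points(0.3, constant_B = 0), "constant_B")
})

test_that("the published sheet reproduces the printed points and range 0-15", {
  sheet <- published_score_sheet()
  f <- sheet$factors
  pts <- function(fac, cat) f$points[f$factor == fac & f$category == cat]
  expect_equal(pts("stroke", "TRUE"), 1L)
  expect_equal(pts("duration", ">=20"), 2L)
  expect_equal(pts("bmi", "overweight"), 0L)
  expect_equal(pts("fpg_cv", "17.6-35.0"), 0L)
  expect_equal(f$points[f$factor == "age"], 0:8)
  expect_equal(sheet$min_total, 0L)
  expect_equal(sheet$max_total, 15L)
  # base categories all score 0
  base <- do.call(rbind, lapply(split(f, f$factor), function(g) g[1, ]))
  expect_true(all(base$points == 0))
})

test_that("recomputing points from the published betas agrees where the arithmetic is unambiguous", {
  sheet <- published_score_sheet()
  f <- sheet$factors
  recomputed <- assign_points(f$beta, f$w, f$w_ref, sheet$constant_B)
  agree <- recomputed == f$points
  # categories whose printed points match the round-half-up quotient
  unambiguous <- !(paste(f$factor, f$category) %in%
                     c("sex male",            # 0.27/0.60 = 0.45 -> 0, printed 1
                       "hypertension TRUE",   # 0.24/0.60 = 0.40 -> 0, printed 1
                       "fpg_cv >=35.0",       # 0.28/0.60 = 0.47 -> 0, printed 1
                       "duration >=20"))      # 1.62/0.60 = 2.70 -> 3, printed 2
  expect_true(all(agree[unambiguous]))
  # the divergent categories are pinned: they differ in the known direction
  expect_equal(recomputed[f$factor == "sex" & f$category == "male"], 0)
  expect_equal(recomputed[f$factor == "hypertension" & f$category == "TRUE"], 0)
  expect_equal(recomputed[f$factor == "fpg_cv" & f$category == ">=35.0"], 0)
  expect_equal(recomputed[f$factor == "duration" & f$category == ">=20"], 3)
})

test_that("total points sum category points over factors", {
  sheet <- published_score_sheet()
  base <- list(age = "35-39", sex = "female", duration = "0", bmi = "normal",
               fpg_cv = "<17.6", stroke = FALSE, hypertension = FALSE)
  expect_equal(total_points(base, sheet), 0L)
  maximal <- list(age = "75-78", sex = "male", duration = ">=20",
                  bmi = "obese", fpg_cv = ">=35.0", stroke = TRUE,
                  hypertension = TRUE)
  expect_equal(total_points(maximal, sheet), 15L)
  # 78-year-old female, all else base: the age band alone
  old_female <- base; old_female$age <- "75-78"
  expect_equal(total_points(old_female, sheet), 8L)
  expect_error(total_points(base[-1], sheet), "missing factor")
  bad <- base; bad$bmi <- "underweight"
  expect_error(total_points(bad, sheet), "unknown category")
})

test_that("sheet construction from a fitted model keeps quotients and bases consistent", {
  d <- derived_default_cohort(3000, seed = 19)
  fit <- fit_cox(d, score_terms)
  sheet <- build_score_sheet(fit)
  f <- sheet$factors
  expect_equal(f$points, as.integer(pmax(floor(f$quotient + 0.5), 0)))
  expect_true(all(f$points[f$w == f$w_ref] == 0))
  expect_equal(sheet$max_total,
               sum(tapply(f$points, f$factor, max)))
  # subject scoring equals the category-wise total
  pts <- score_subjects(d, sheet)
  expect_true(all(pts >= sheet$min_total & pts <= sheet$max_total))
  i <- which.max(d$age)
  age_labels <- c("35-39", "40-44", "45-49", "50-54", "55-59", "60-64",
                  "65-69", "70-74", "75-78")
  manual <- total_points(list(
    age = age_labels[d$age_band[i] + 1],
    sex = d$sex[i], duration = as.character(d$duration_cat[i]),
    bmi = as.character(d$bmi_cat[i]), fpg_cv = as.character(d$fpgcv_cat[i]),
    stroke = d$stroke[i], hypertension = d$hypertension[i]), sheet)
  expect_equal(pts[i], manual)
})

test_that("the risk table is monotone in points and horizon and anchored at the mean", {
  f <- fake_cox_fit("age", 0.12, means = 62.5, s0 = c(0.99, 0.97, 0.90))
  sheet <- build_score_sheet(f)

  # mean anchor: the row at the mean point total gets the mean-profile
  # risk 1 - S0(t) exactly
  rt <- build_risk_table(sheet, f, anchor = "mean", mean_points = 5)
  expect_equal(rt$point_total, 0:8)
  expect_equal(rt$risk_3y[rt$point_total == 5], 1 - 0.99, tolerance = 1e-12)
  expect_equal(rt$risk_10y[rt$point_total == 5], 1 - 0.90, tolerance = 1e-12)

  # base anchor: mean age 62.5 puts the 5-point row exactly at the mean
  # linear predictor (0.12 x 37.5 + 0.6 x 5 = 0.12 x 62.5)
  rtb <- build_risk_table(sheet, f, anchor = "base")
  expect_equal(rtb$risk_3y[rtb$point_total == 5], 1 - 0.99, tolerance = 1e-12)
  expect_equal(as.data.frame(rtb), as.data.frame(rt), tolerance = 1e-12)

  for (col in c("risk_3y", "risk_5y", "risk_10y"))
    expect_true(all(diff(rt[[col]]) > 0))
  expect_true(all(rt$risk_5y >= rt$risk_3y & rt$risk_10y >= rt$risk_5y))
  expect_true(all(rt$risk_3y >= 0 & rt$risk_10y <= 1))
  bad <- f; bad$baseline_survival <- c(1.2, 0.9, 0.8)
  expect_error(build_risk_table(sheet, bad, anchor = "base"),
               "baseline survival")
  expect_error(build_risk_table(sheet, f, anchor = "mean"), "mean_points")
})

test_that("sheets and risk tables round-trip through their writers", {
  d <- derived_default_cohort(1500, seed = 23)
  fit <- fit_cox(d, score_terms)
  sheet <- build_score_sheet(fit)
  rt <- build_risk_table(sheet, fit, anchor = "mean",
                         mean_points = mean(score_subjects(d, sheet)))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_score_sheet(sheet, p1)
  write_risk_table(rt, p2)
  sheet2 <- read_score_sheet(p1)
  expect_equal(sheet2$constant_B, sheet$constant_B, tolerance = 1e-12)
  expect_equal(sheet2$factors$points, sheet$factors$points)
  expect_equal(sheet2$max_total, sheet$max_total)
  rt2 <- read_risk_table(p2)
  expect_equal(as.data.frame(rt2), as.data.frame(rt), tolerance = 1e-10)
  # risks looked up by points match the table
  expect_equal(predict_risk(rt, c(0, 3, sheet$max_total), 10),
               rt$risk_10y[c(1, 4, nrow(rt))])
})
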