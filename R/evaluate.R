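#' Random derivation/validation split
#'
#' Disjoint, exhaustive partition at an integer ratio (default 2:1),
#' deterministic under the seed; group sizes differ from the exact ratio
#' by less than one subject.
#'
#' @param cohort cohort data frame (>= 3 rows).
#' @param ratio integer pair, derivation : validation.
#' @param seed integer seed.
#' @return list with `derivation` and `validation` data frames.
#' @export
split_cohort <- function(cohort, ratio = c(2, 1), seed = 1) {
  n <- nrow(cohort)
  if (n < 3) stop_invalid("cohort", "needs at least 3 subjects")
  if (length(ratio) != 2 || any(ratio <= 0))
    stop_invalid("ratio", "must be two positive integers")
  n_deriv <- round(n * ratio[1] / sum(ratio))
  idx <- with_seed(seed, sample.int(n, n_deriv))
  list(derivation = cohort[sort(idx), , drop = FALSE],
       validation = cohort[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Standardized difference (Cohen's d) between two groups
#'
#' Continuous: (mean_a - mean_b) / pooled SD with pooled SD =
#' sqrt((sd_a^2 + sd_b^2) / 2). Binary: difference in proportions over the
#' pooled binomial SD sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2). Sign convention
#' is a - b.
#'
#' @param a,b numeric (or logical, for binary) vectors, both non-empty.
#' @param type "continuous" or "binary".
#' @return the standardized difference; 0 with a warning when the pooled
#'   SD is zero but the means agree.
#' @export
standardized_difference <- function(a, b, type = c("continuous", "binary")) {
  type <- match.arg(type)
  if (!length(a) || !length(b)) stop_invalid("a/b", "both groups must be non-empty")
  a <- as.numeric(a); b <- as.numeric(b)
  if (type == "binary") {
    pa <- mean(a); pb <- mean(b)
    s <- sqrt((pa * (1 - pa) + pb * (1 - pb)) / 2)
    num <- pa - pb
  } else {
    s <- sqrt((stats::var(a) + stats::var(b)) / 2)
    num <- mean(a) - mean(b)
  }
  if (s == 0) {
    if (num == 0) {
      warning("zero pooled SD with equal means: standardized difference set to 0")
      return(0)
    }
    stop_invalid("a/b", "zero pooled SD with unequal means")
  }
  num / s
}

#' Fixed-horizon outcome classification
#'
#' A subject is an `event` if CKD occurred by the horizon, a `non-event`
#' if followed to (or beyond) the horizon without CKD, and `excluded` if
#' censored before the horizon without CKD.
#'
#' @param time follow-up years.
#' @param event 0/1 event indicator (1 = CKD).
#' @param horizon horizon t in years.
#' @return character vector in {"event", "non-event", "excluded"}.
#' @export
horizon_outcome <- function(time, event, horizon) {
  ifelse(event == 1 & time <= horizon, "event",
         ifelse(time >= horizon, "non-event", "excluded"))
}

#' AUC with DeLong confidence interval
#'
#' Mann-Whitney concordance of score versus binary outcome, ties counted
#' one half; the 95% CI uses the DeLong variance.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param outcomes binary outcomes (0/1 or logical).
#' @return list with `auc`, `lower`, `upper`, `n_cases`, `n_controls`.
#' @export
auc_ci <- function(scores, outcomes) {
  y <- as.integer(as.logical(outcomes))
  if (length(unique(y)) < 2)
    stop_invalid("outcomes", "both classes must be present (AUC undefined)")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), lower = ci[1], upper = ci[3],
       n_cases = sum(y == 1), n_controls = sum(y == 0))
}

# quantile-based risk groups, falling back to grouping by distinct
# predicted value when there are too few distinct risks for the quantiles
risk_groups <- function(p, n_groups) {
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(br) >= 3) cut(p, breaks = br, include.lowest = TRUE)
  else factor(p)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects by quantiles of predicted risk (deciles by default);
#' chi^2 = sum (O_g - E_g)^2 / (E_g (1 - E_g / n_g)), p from the upper
#' chi^2 tail. Groups with zero expected events are merged into their
#' lower neighbor with a warning.
#'
#' The reference degrees of freedom depend on where the predictions come
#' from: `df = "fitted"` (groups - 2, the classical calibration for
#' probabilities estimated in-sample by the model under test) or
#' `df = "external"` (groups, appropriate when a fixed, previously built
#' model is validated on data that played no part in its estimation, as
#' on a validation set).
#'
#' @param predicted predicted risks in [0, 1].
#' @param observed binary outcomes.
#' @param n_groups number of risk groups (>= 3; default 10).
#' @param df "fitted" (groups - 2) or "external" (groups).
#' @return list with `chisq`, `df`, `p` and the per-group `table`
#'   (n, expected, observed).
#' @export
hosmer_lemeshow <- function(predicted, observed, n_groups = 10,
                            df = c("fitted", "external")) {
  df <- match.arg(df)
  p <- as.numeric(predicted)
  y <- as.integer(as.logical(observed))
  if (n_groups < 3) stop_invalid("n_groups", "must be >= 3")
  if (any(p < 0 | p > 1)) stop_invalid("predicted", "risks must lie in [0, 1]")
  g <- risk_groups(p, n_groups)
  tab <- data.frame(
    n = as.integer(tapply(y, g, length)),
    expected = as.numeric(tapply(p, g, sum)),
    observed = as.integer(tapply(y, g, sum))
  )
  tab <- tab[!is.na(tab$n), , drop = FALSE]
  while (any(tab$expected == 0) && nrow(tab) > 1) {
    warning("group with zero expected events merged into its neighbor")
    i <- which(tab$expected == 0)[1]
    j <- if (i == 1) 2 else i - 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab <- tab[-i, , drop = FALSE]
  }
  denom <- tab$expected * (1 - tab$expected / tab$n)
  denom[denom <= 0] <- NA
  terms <- (tab$observed - tab$expected)^2 / denom
  terms[is.na(terms) & tab$observed == tab$expected] <- 0
  chisq <- sum(terms, na.rm = TRUE)
  dof <- max(nrow(tab) - if (df == "fitted") 2 else 0, 1)
  list(chisq = chisq, df = dof,
       p = stats::pchisq(chisq, dof, lower.tail = FALSE), table = tab)
}

#' Observed versus expected events by decile of predicted risk
#'
#' @param predicted predicted risks in [0, 1].
#' @param observed binary outcomes.
#' @param n_groups number of groups (default 10).
#' @return data frame per group: `n`, `mean_predicted`, `expected` (sum of
#'   predicted risks), `observed` (event count). The `expected` column
#'   sums to the total of all predictions.
#' @export
calibration_deciles <- function(predicted, observed, n_groups = 10) {
  p <- as.numeric(predicted)
  y <- as.integer(as.logical(observed))
  if (any(p < 0 | p > 1)) stop_invalid("predicted", "risks must lie in [0, 1]")
  g <- risk_groups(p, n_groups)
  out <- data.frame(
    decile = levels(g),
    n = as.integer(tapply(y, g, length)),
    mean_predicted = as.numeric(tapply(p, g, mean)),
    expected = as.numeric(tapply(p, g, sum)),
    observed = as.integer(tapply(y, g, sum))
  )
  out[!is.na(out$n), , drop = FALSE]
}

#' Evaluate a fitted score on derivation and validation sets
#'
#' Computes, per set and horizon: the number of evaluable subjects
#' (subjects censored before the horizon without CKD are excluded), the
#' AUC of the integer point total with DeLong CI, the Hosmer-Lemeshow
#' test on the risk-table predictions, and the observed-versus-expected
#' calibration deciles. Baseline comparability between the two sets is
#' summarized by standardized differences.
#'
#' @param derivation,validation derived cohorts ([derive_covariates()]).
#' @param sheet a `score_sheet`.
#' @param risk_table the matching `risk_table`.
#' @param horizons years (default the risk-table horizons 3, 5, 10).
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return an `evaluation_report`: `split_sizes`,
#'   `standardized_differences`, `auc` (data frame), `hl` (data frame),
#'   `calibration` (named list of decile tables).
#' @export
evaluate_model <- function(derivation, validation, sheet, risk_table,
                           horizons = c(3, 5, 10), hl_groups = 10) {
  smd_vars <- list(
    age = "continuous", bmi = "continuous", diabetes_duration = "continuous",
    fpg_cv = "continuous", stroke = "binary", hypertension = "binary"
  )
  smd <- vapply(names(smd_vars), function(v)
    standardized_difference(derivation[[v]], validation[[v]],
                            smd_vars[[v]]), numeric(1))

  sets <- list(derivation = derivation, validation = validation)
  auc_rows <- list(); hl_rows <- list(); calib <- list()
  for (set_name in names(sets)) {
    d <- sets[[set_name]]
    pts <- score_subjects(d, sheet)
    for (t in horizons) {
      oc <- horizon_outcome(d$follow_up, d$ckd, t)
      keep <- oc != "excluded"
      y <- oc[keep] == "event"
      a <- auc_ci(pts[keep], y)
      auc_rows[[length(auc_rows) + 1]] <-
        data.frame(set = set_name, horizon = t, n = sum(keep),
                   events = sum(y), auc = a$auc, lower = a$lower,
                   upper = a$upper)
      pr <- predict_risk(risk_table, pts[keep], t)
      hl <- hosmer_lemeshow(pr, y, hl_groups,
                            df = if (set_name == "validation") "external"
                                 else "fitted")
      hl_rows[[length(hl_rows) + 1]] <-
        data.frame(set = set_name, horizon = t, chisq = hl$chisq,
                   df = hl$df, p = hl$p)
      calib[[sprintf("%s_%gy", set_name, t)]] <- calibration_deciles(pr, y,
                                                                     hl_groups)
    }
  }
  structure(list(
    split_sizes = c(derivation = nrow(derivation),
                    validation = nrow(validation)),
    standardized_differences = smd,
    auc = do.call(rbind, auc_rows),
    hl = do.call(rbind, hl_rows),
    calibration = calib
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report (derivation n = %d, validation n = %d)\n",
              x$split_sizes["derivation"], x$split_sizes["validation"]))
  cat("Standardized differences (derivation - validation):\n")
  print(round(x$standardized_differences, 3))
  cat("Horizon AUC (integer point total):\n")
  a <- x$auc
  a$auc <- round(a$auc, 3); a$lower <- round(a$lower, 3)
  a$upper <- round(a$upper, 3)
  print(a, row.names = FALSE)
  cat("Hosmer-Lemeshow calibration:\n")
  h <- x$hl
  h$chisq <- round(h$chisq, 2); h$p <- signif(h$p, 3)
  print(h, row.names = FALSE)
  invisible(x)
}
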