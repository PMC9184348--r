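#' Fit a Cox proportional-hazards model for incident CKD
#'
#' Wraps a partial-likelihood fit with Breslow handling of tied event
#' times, and collects everything the score builder needs: per-term
#' log-hazard ratios with standard errors (observed information), Wald
#' p-values, hazard ratios with 95% CIs, the design-column means, and the
#' Breslow baseline survival S0(t) at the requested horizons evaluated at
#' the mean covariate profile.
#'
#' @param data a derived cohort ([derive_covariates()]), or any data frame
#'   with `follow_up` (years) and `ckd` (0/1) columns plus the model
#'   terms.
#' @param terms character vector of column names entering the model
#'   (factors expand to treatment-contrast indicators).
#' @param horizons years at which to evaluate baseline survival.
#' @return an object of class `cox_fit` with elements `terms`, `beta`,
#'   `se`, `p_value`, `hr`, `hr_lower`, `hr_upper`, `covariate_means`,
#'   `horizons`, `baseline_survival`, `log_partial_likelihood`, `n`,
#'   `n_events`, and the underlying `survival::coxph` object in `$model`.
#' @export
fit_cox <- function(data, terms, horizons = c(3, 5, 10)) {
  stopifnot(is.data.frame(data), length(terms) >= 1)
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms))
    stop_invalid("terms", paste("not in data:", paste(missing_terms, collapse = ", ")))
  if (sum(data$ckd) < 1)
    stop_invalid("data", "at least one event is required")
  for (tm in terms) {
    v <- data[[tm]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop_invalid("terms", sprintf("'%s' is constant within the sample", tm))
  }
  fml <- stats::as.formula(paste("survival::Surv(follow_up, ckd) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "breslow", x = TRUE,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("Cox fit failed to estimate all coefficients (singular design); ",
         "gradient/information diagnostics unavailable", call. = FALSE)
  capped <- abs(beta) > 15
  if (any(capped)) {
    warning("possible complete separation: coefficient(s) capped at |beta| = 15: ",
            paste(names(beta)[capped], collapse = ", "))
    beta[capped] <- sign(beta[capped]) * 15
  }
  se <- sqrt(diag(fit$var))
  z <- beta / se
  # survfit() centers the curve at coxph's internal reference (continuous
  # covariates at their means, factor indicators at 0); re-center the
  # Breslow baseline survival at the mean covariate profile, where
  # indicator means are the sample proportions
  xbar <- colMeans(fit$x)
  sf <- survival::survfit(fit)
  surv_ref <- summary(sf, times = horizons, extend = TRUE)$surv
  s0 <- surv_ref^exp(sum(beta * (xbar - fit$means)))

  structure(list(
    terms = names(beta), beta = unname(beta), se = unname(se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    hr = unname(exp(beta)),
    hr_lower = unname(exp(beta - 1.96 * se)),
    hr_upper = unname(exp(beta + 1.96 * se)),
    covariate_means = unname(xbar),
    horizons = horizons, baseline_survival = s0,
    log_partial_likelihood = fit$loglik[length(fit$loglik)],
    n = fit$n, n_events = fit$nevent,
    formula_terms = terms, model = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: %d subjects, %d events\n",
              x$n, x$n_events))
  tab <- data.frame(term = x$terms, beta = round(x$beta, 4),
                    se = round(x$se, 4),
                    HR = round(x$hr, 3),
                    `95% CI` = sprintf("(%.3f, %.3f)", x$hr_lower, x$hr_upper),
                    p = signif(x$p_value, 3), mean = round(x$covariate_means, 4),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("Baseline survival S0(t) at mean profile: %s\n",
              paste(sprintf("%g y: %.5f", x$horizons, x$baseline_survival),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize / read a Cox fit
#'
#' JSON round-trip of the fields consumed by the score builder (the
#' underlying model object is not serialized).
#' @param fit a `cox_fit`.
#' @param path JSON file path.
#' @export
write_cox_fit <- function(fit, path) {
  jsonlite::write_json(fit[c("terms", "beta", "se", "p_value", "hr",
                             "hr_lower", "hr_upper", "covariate_means",
                             "horizons", "baseline_survival",
                             "log_partial_likelihood", "n", "n_events",
                             "formula_terms")],
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cox_fit
#' @export
read_cox_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "cox_fit")
}

#' Crude (single-factor) hazard ratios
#'
#' One single-factor Cox model per stratified factor, with the reference
#' stratum reported at HR = 1.00.
#'
#' @param data a derived cohort with `follow_up` and `ckd`.
#' @param factor name of a factor (or logical) column; the first level is
#'   the reference.
#' @return data frame with `stratum`, `hr`, `lower`, `upper`, `p`
#'   (reference row: HR 1, CI and p `NA`).
#' @export
crude_hazard_ratios <- function(data, factor) {
  g <- data[[factor]]
  if (is.logical(g)) g <- base::factor(g, c(FALSE, TRUE), c("No", "Yes"))
  g <- as.factor(g)
  empty <- levels(g)[table(g) == 0]
  if (length(empty)) {
    warning("empty stratum skipped: ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  d <- data
  d$..g <- g
  fit <- fit_cox(d, "..g")
  lev <- levels(g)
  data.frame(
    stratum = lev,
    hr = c(1, fit$hr), lower = c(NA, fit$hr_lower),
    upper = c(NA, fit$hr_upper), p = c(NA, fit$p_value),
    row.names = NULL
  )
}

# grouped Wald test over the design columns belonging to one model term
term_wald_p <- function(fit) {
  asg <- fit$assign                      # list: term label -> column indices
  b <- stats::coef(fit)
  V <- fit$var
  vapply(asg, function(idx) {
    chi <- drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% b[idx])
    stats::pchisq(chi, df = length(idx), lower.tail = FALSE)
  }, numeric(1))
}

#' Two-stage variable selection for the CKD model
#'
#' Stage 1 screens each candidate with a single-term Cox model (grouped
#' Wald test for multi-level factors); candidates with p < `screening_alpha`
#' (default 0.20) enter. Perfectly or near-collinear candidates (any pair
#' of design columns with |r| > `collinearity_r`) are flagged and the one
#' with the larger univariable p is dropped. Stage 2 is backward
#' elimination: the multivariable model is refit repeatedly, removing the
#' largest-p term while it is >= `retention_alpha` (default 0.05), until
#' every remaining term is significant.
#'
#' @param data derived cohort with `follow_up` and `ckd`.
#' @param candidates character vector of candidate term names.
#' @param screening_alpha univariable entry threshold.
#' @param retention_alpha multivariable retention threshold.
#' @param collinearity_r absolute correlation above which two candidates
#'   may not enter jointly.
#' @param horizons passed to [fit_cox()] for the final model.
#' @return list with `trace` (class `selection_trace`: `univariable_p`,
#'   `candidates_passing`, `collinearity_flags`, `elimination_steps`,
#'   `final_terms`) and `fit` (the final `cox_fit`, or `NULL` if every
#'   candidate was eliminated).
#' @export
select_model <- function(data, candidates, screening_alpha = 0.20,
                         retention_alpha = 0.05, collinearity_r = 0.8,
                         horizons = c(3, 5, 10)) {
  stopifnot(retention_alpha <= screening_alpha)
  uni <- vapply(candidates, function(tm) {
    f <- fit_cox(data, tm, horizons = horizons)
    p <- term_wald_p(f$model)
    unname(p[1])
  }, numeric(1))
  passing <- candidates[uni < screening_alpha]

  flags <- list()
  if (length(passing) > 1) {
    fml <- stats::as.formula(paste("~", paste(passing, collapse = " + ")))
    mm <- stats::model.matrix(fml, data = data)
    labs <- attr(stats::terms(fml), "term.labels")
    keep <- attr(mm, "assign") > 0
    X <- mm[, keep, drop = FALSE]
    colterm <- labs[attr(mm, "assign")[keep]]
    r <- suppressWarnings(stats::cor(X))
    drop_set <- character(0)
    for (i in seq_len(ncol(X))) for (j in seq_len(ncol(X))) {
      if (i < j && colterm[i] != colterm[j] &&
          is.finite(r[i, j]) && abs(r[i, j]) > collinearity_r) {
        pair <- c(colterm[i], colterm[j])
        victim <- pair[which.max(uni[pair])]
        flags[[length(flags) + 1]] <- list(pair = pair, r = r[i, j],
                                           dropped = victim)
        drop_set <- union(drop_set, victim)
      }
    }
    if (length(drop_set)) {
      warning("collinear candidate(s) dropped before multivariable fitting: ",
              paste(drop_set, collapse = ", "))
      passing <- setdiff(passing, drop_set)
    }
  }

  steps <- list()
  current <- passing
  fit <- NULL
  while (length(current)) {
    fit <- fit_cox(data, current, horizons = horizons)
    p <- term_wald_p(fit$model)
    worst <- which.max(p)
    if (p[worst] < retention_alpha) break
    steps[[length(steps) + 1]] <- list(term = names(p)[worst],
                                       p = unname(p[worst]))
    current <- setdiff(current, names(p)[worst])
    fit <- NULL
  }
  if (!length(current)) {
    warning("all candidates eliminated; returning an empty model")
    fit <- NULL
  }

  trace <- structure(list(
    univariable_p = uni, candidates_passing = passing,
    collinearity_flags = flags, elimination_steps = steps,
    final_terms = current
  ), class = "selection_trace")
  list(trace = trace, fit = fit)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Two-stage Cox variable selection\n")
  cat("  univariable p:\n")
  print(signif(x$univariable_p, 3))
  cat("  passing screen:", paste(x$candidates_passing, collapse = ", "), "\n")
  if (length(x$collinearity_flags))
    for (f in x$collinearity_flags)
      cat(sprintf("  collinearity: %s ~ %s (r = %.2f) -> dropped %s\n",
                  f$pair[1], f$pair[2], f$r, f$dropped))
  for (s in x$elimination_steps)
    cat(sprintf("  removed %s (p = %.3f)\n", s$term, s$p))
  cat("  final terms:", paste(x$final_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection trace to JSON
#' @param trace a `selection_trace`.
#' @param path JSON file path.
#' @export
write_selection_trace <- function(trace, path) {
  jsonlite::write_json(unclass(trace), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Proportional-hazards diagnostic
#'
#' Scaled Schoenfeld residual tests (per term and global) for the
#' proportional-hazards assumption; reported, never used to alter the
#' model. Skipped with a warning when fewer than 10 events are available.
#'
#' @param fit a `cox_fit` from [fit_cox()].
#' @return data frame with `term`, `chisq`, `df`, `p` (last row: GLOBAL),
#'   or `NULL` when skipped.
#' @export
check_proportional_hazards <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (is.null(fit$model) || length(fit$beta) == 0) return(NULL)
  if (fit$n_events < 10) {
    warning("fewer than 10 events: proportional-hazards diagnostic skipped")
    return(NULL)
  }
  z <- survival::cox.zph(fit$model)
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}
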