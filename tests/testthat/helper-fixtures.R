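# shared fixtures and independent oracles

# small survival fixture with a single binary covariate; times chosen so
# that one pair of event times is tied (exercises Breslow tie handling)
tiny_surv_fixture <- function() {
  data.frame(
    follow_up = c(1, 2, 2, 4, 5, 6),
    ckd       = c(1, 1, 1, 0, 1, 0),
    x         = c(1, 1, 0, 1, 0, 0)
  )
}

# explicit Breslow log partial likelihood for one covariate, written out
# from the definition (independent of any survival-package code)
breslow_logpl <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    ev <- which(time == t & status == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[ev]) -
      length(ev) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force maximizer of the written-out partial likelihood
breslow_oracle_beta <- function(time, status, x) {
  stats::optimize(function(b) breslow_logpl(b, time, status, x),
                  interval = c(-10, 10), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# all-pairs Mann-Whitney concordance (ties = 1/2), O(n^2)
brute_force_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# minimal cox_fit-shaped object for score arithmetic tests
fake_cox_fit <- function(terms, beta, means = rep(0, length(beta)),
                         horizons = c(3, 5, 10),
                         s0 = c(0.99, 0.98, 0.95)) {
  structure(list(terms = terms, beta = beta, se = rep(0.1, length(beta)),
                 p_value = rep(0.01, length(beta)),
                 hr = exp(beta), hr_lower = exp(beta - 0.2),
                 hr_upper = exp(beta + 0.2),
                 covariate_means = means, horizons = horizons,
                 baseline_survival = s0, log_partial_likelihood = 0,
                 n = 0L, n_events = 0L, model = NULL),
            class = "cox_fit")
}

small_default_cohort <- function(n = 1200, seed = 7) {
  suppressWarnings(generate_cohort(cohort_spec(n_subjects = n, seed = seed)))
}

derived_default_cohort <- function(n = 1200, seed = 7) {
  suppressWarnings(derive_covariates(small_default_cohort(n, seed)))
}

score_terms <- c("age", "sex", "duration_cat", "bmi_cat", "fpgcv_cat",
                 "stroke", "hypertension")
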