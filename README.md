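# ckdscore

Derivation and validation of a points-based clinical risk score for
chronic kidney disease (CKD) in adults with type 2 diabetes (T2DM),
packaged as a fully testable pipeline with a seeded synthetic-cohort
generator.

## Who this is for

Biostatisticians and clinical epidemiologists building or studying
Framingham-style integer scoring systems for time-to-event outcomes:
the package contains every stage — cohort simulation, clinical variable
derivation, Cox modeling with variable selection, Sullivan points
construction, and discrimination/calibration evaluation — as separately
callable, separately tested functions.

## The method

A Cox proportional-hazards model is fitted on a derivation set
(2:1 random split) after two-stage selection: univariable screening at
*P* < 0.20, then backward elimination at *P* < 0.05 with a pairwise
collinearity guard. The fitted model is converted into an integer score
by the Framingham/Sullivan recipe. Risk factors are categorized with
reference values *W<sub>ij</sub>* (5-year age bands with band-midpoint
offsets; indicators elsewhere), a base profile scores 0, and

> Point<sub>ij</sub> = (β<sub>i</sub> (W<sub>ij</sub> − W<sub>iREF</sub>)) / B,
> rounded half-up, floored at 0,

with the constant *B* = 5 × β<sub>age</sub> (one point = the hazard of
five years of age). Point totals map to absolute risks through the
Breslow baseline survival at the mean covariate profile:

> p̂(t) = 1 − S₀(t)<sup>exp(u(P))</sup>,  u(P) = B (P − P̄)

(mean-anchored by default; a base-profile anchor is available). The
score's predictors are age, sex, diabetes duration, BMI, first-year
fasting-plasma-glucose variability (visit-adjusted coefficient of
variation, CV × √((n−1)/n)), stroke and hypertension; CKD is
eGFR < 60 mL/min/1.73 m² (modified MDRD-type equation for Chinese
adults) and/or dipstick proteinuria ≥ 1+.

Evaluation is by fixed-horizon (3/5/10-year) ROC AUC with DeLong
confidence intervals and Hosmer–Lemeshow calibration with
observed-versus-expected deciles.

## Worked example

```r
library(ckdscore)

cfg <- pipeline_config(
  cohort_spec = cohort_spec(n_subjects = 2051, seed = 42),
  split_seed = 7
)
res <- run_pipeline(cfg, quiet = TRUE)
res$report
```

Output from this exact run:

```
Evaluation report (derivation n = 1367, validation n = 684)
Standardized differences (derivation - validation):
              age               bmi diabetes_duration            fpg_cv 
            0.032             0.006             0.012             0.015 
           stroke      hypertension 
            0.016             0.050 
Horizon AUC (integer point total):
        set horizon    n events   auc lower upper
 derivation       3 1353     95 0.765 0.716 0.813
 derivation       5 1344    188 0.808 0.776 0.840
 derivation      10 1319    356 0.800 0.773 0.827
 validation       3  677     35 0.806 0.736 0.875
 validation       5  672     72 0.782 0.728 0.836
 validation      10  659    162 0.807 0.770 0.844
```

Reading this: baseline covariates are comparable across the split (all
standardized differences ≤ 0.05); the integer score discriminates
3–10-year CKD onset with AUCs near 0.8 in both sets (values above 0.7
are conventionally "good"). `res$sheet` prints the score sheet with each
category's β, raw quotient and integer points; `res$risk_table` maps
every point total (0 to the sheet's maximum) to 3/5/10-year risks, e.g.
a subject scoring 0 points has a fraction-of-a-percent 3-year risk while
the maximal score approaches certainty by 10 years.

The published score sheet itself (with its printed points, total range
0–15) ships as `published_score_sheet()`, and the published stratified
incidence inputs as `published_incidence_counts()`:

```r
incidence_rate(504, 17479)   # 28.83 events per 1000 person-years
total_points(list(age = "75-78", sex = "male", duration = ">=20",
                  bmi = "obese", fpg_cv = ">=35.0", stroke = TRUE,
                  hypertension = TRUE), published_score_sheet())  # 15
```

A thin command-line front end over the same functions lives at
`inst/cli/ckdscore.R` (`simulate`, `derive`, `fit`, `build-score`,
`run-all`), driven by a YAML configuration
(see `?load_pipeline_config`).

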