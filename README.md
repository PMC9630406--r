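# t1dstage

Metabolic staging, progression-likelihood scoring and screening economics
for presymptomatic type 1 diabetes in childhood population screening.

Children with two or more confirmed islet autoantibodies (IAA, GADA,
IA-2A, ZnT8A) have presymptomatic type 1 diabetes. Population screening
programmes stage them by OGTT and HbA1c — stage 1 (normoglycaemia),
stage 2 (dysglycaemia), stage 3 (clinical diabetes) — and need to know
which stage 1 children will progress quickly, and what it costs to
recruit a prevention trial through screening. This package is for
biostatisticians and trial designers working on such programmes. It
implements:

* **Staging** under the 2015 consensus criteria and the revised ADA
  criteria, with exact unit conversions (mg/dl ↔ mmol/l, % ↔ mmol/mol).
* **The progression likelihood score** in both published forms, with
  HbA1c in %, the 90-min OGTT glucose (OGTT90) in mg/dl, and IA-2A as a
  titre category (negative = 0, tertiles 3–100, 100–290, > 290 AU = 1–3):

  ```
  CPH: exp[(HbA1c − 5.233)·1.125 + (OGTT90 − 107.6)·0.0195 + (IA2Acat − 1.27)·0.662]
  LR:  2.048·HbA1c + 0.034·OGTT90 + 0.006·IA2A(titre, AU)
  ```

  plus 30th/90th-centile substaging of stage 1 into 1a_low / 1a_mid / 1b
  (fixed thresholds: CPH > 4.0, LR > 17.1) and first-crossing rescoring
  over follow-up visits.
* **Survival analysis**: Kaplan–Meier progression risk with Greenwood
  variance and log(−log) intervals, logrank tests, and the annualised
  risk conversion a = 1 − √(1 − R₂).
* **Score refitting**: univariable Cox screen → multivariable backward
  elimination (Efron ties), and the penalised-logistic + random-forest
  importance route with 10-fold CV on the binary 2-year outcome.
* **Evaluation**: decile risk/sensitivity curves, threshold diagnostics
  (sensitivity, specificity, PPV, LR+, LR−, diagnostic OR in both
  algebraic forms), percentile bootstrap CIs.
* **Trial economics**: sample size, screening requirement, cost and case
  yield (exact cent arithmetic, reporting roundings at print time only).
* **A synthetic-cohort generator** whose truth is the published score
  acting as a proportional-hazards linear predictor, so every stage of
  the pipeline is testable without individual-level clinical data.

## Worked example

```r
library(t1dstage)

# one child's staging OGTT (mg/dl at 0/30/60/90/120 min) and HbA1c
classify_stage(c(120, 150, 170, 160, 150), hba1c_pct = 5.4)$stage
#> [1] 2

# progression likelihood score: a high-risk stage 1 child
cph_score(hba1c = 6.0, ogtt90 = 160, ia2a_cat = 3)
#> [1] 20.69589          # > 4.0, so substage 1b
lr_score(6.0, 150, ia2a_titre = 400)
#> [1] 19.788            # > 17.1, so substage 1b on the LR form too

# a full synthetic screening round
cfg <- cohort_config(seed = 20150201L)
pop <- simulate_screened_population(cfg)
staged <- simulate_progression(pop[pop$multi_aab, ], cfg)
prevalence_ci(nrow(staged), nrow(pop))$estimate * 100
#> [1] 0.290039          # 448 of 154,462 children confirmed positive

s2 <- staged[staged$stage_at_staging == 2, ]
r <- risk_at(km_fit(s2$event_time_years, s2$event), t = 2)
round(100 * c(r$risk, r$ci_low, r$ci_high), 1)
#> [1] 55.4 34.9 78.1    # 2-year stage 2 progression risk (%), 95% CI
round(100 * annualised_risk(r$risk))
#> [1] 33                # per-year risk compounding to the 2-year risk

# what a powered prevention trial costs to recruit by screening
plan <- trial_plan(n_enrol = 154, participation_rate = 0.5,
                   eligible_frequency = 59 / 154462)
c(plan$n_eligible_needed, plan$n_screen, plan$total_cost_millions,
  plan$expected_stage3_detected, plan$cost_per_identified)
#> [1]      308   810000     17.6      219    33400
```

Reading: enrolling 154 children at 50% participation needs 308 eligible
(stage 1b or stage 2) children; at their screening frequency that means
screening ~810,000 children at €21.73 each (€17.6M), which would also
uncover 219 children with undiagnosed clinical diabetes — €33,400 per
high-risk or diabetic child identified.

## The analysis workflow

`analysis/` contains numbered drivers that run the whole study pipeline
on a synthetic cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # screening round + follow-up
Rscript analysis/02_stage_classify.R     # 2015 vs revised-ADA staging
Rscript analysis/03_score_substage.R     # scores, substaging, rescoring
Rscript analysis/04_progression_risk.R   # KM risks, logrank, at-risk table
Rscript analysis/05_refit_models.R       # Cox + penalised-LR refits
Rscript analysis/06_evaluate_trial.R     # decile curve, diagnostics, costs
```

## Vignette

`vignettes/progression-staging-methods.Rmd` documents the staging rules,
the score semantics, what the synthetic-cohort generator does and does
not emulate, the calibration constants, and the design decisions taken
where the published procedure is underspecified.
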