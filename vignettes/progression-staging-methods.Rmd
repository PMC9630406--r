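---
title: "Staging, progression scoring and screening economics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging, progression scoring and screening economics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dstage)
```

## The problem

Children who carry two or more confirmed islet autoantibodies have
presymptomatic type 1 diabetes and will, with near certainty, eventually
develop the clinical disease. Public-health screening programmes can find
these children years before onset, stage them metabolically (stage 1:
normoglycaemia; stage 2: dysglycaemia; stage 3: clinical diabetes), and
counsel or recruit them into prevention trials. Two quantitative problems
follow. First, most screened-positive children are stage 1 with a low
short-term risk, so trials of late-stage disease need a way to find the
stage 1 minority that progresses as fast as stage 2. Second, the
feasibility of trial recruitment through population screening is an
arithmetic question: how many children must be screened, at what cost, to
enrol a powered trial. This package implements both: a rule-based staging
classifier, a composite progression likelihood score with centile-based
substaging (stage 1a/1b), Kaplan–Meier risk estimation, the
score-(re)building procedure, score evaluation, and the
screening/recruitment/cost model — all exercisable on a synthetic-cohort
generator because individual-level data from such programmes are not
publicly deposited.

## Staging rules

Staging consumes an OGTT (plasma glucose at 0, 30, 60, 90, 120 min) and
HbA1c. Internally all comparisons are done in mg/dl and mmol/mol;
`glucose_mgdl_to_mmoll()` and friends convert (glucose by the molar mass
18.016; HbA1c by the IFCC master equation `10.929 * (% - 2.15)`), and a
`1e-9` comparison tolerance keeps values sitting exactly on a printed
bound from flipping category after a unit round trip. Dysglycaemia bands
are inclusive at both printed endpoints (110–125 mg/dl fasting under the
2015 consensus, 100–125 under the revised ADA criteria, 140–199 at 2 h);
diabetic thresholds use the printed operators (fasting ≥ 126, 2 h ≥ 200,
HbA1c > 48 mmol/mol). Values falling between the printed interval tops
and the diabetic thresholds (e.g. fasting 125.5 mg/dl) are classified by
the mg/dl-primary convention: they are neither dysglycaemic nor diabetic,
hence stage 1. The revised-ADA ≥ 10% HbA1c-rise rule is computed relative
to the earliest supplied HbA1c. Glycaemic stage 3 criteria carry a
`requires_confirmation` flag rather than re-evaluating a second record,
unless the caller states the result is confirmed.

## The progression likelihood score

The score exists in two forms, both functions of HbA1c (%), the 90-min
OGTT glucose (mg/dl), and IA-2A autoantibody level:

* CPH form: `exp[(HbA1c − 5.233)·1.125 + (OGTT90 − 107.6)·0.0195 +
  (IA2Acat − 1.27)·0.662]`, with IA-2A entering as an ordinal category
  (0 negative, then titre tertiles 3–100, 100–290, > 290 AU). The log of
  the score is exactly the centered Cox linear predictor, so the score is
  a relative hazard.
* LR form: `2.048·HbA1c + 0.034·OGTT90 + 0.006·IA2A` with IA-2A as the
  raw titre in AU. The 0.006-per-AU magnitude is only consistent with raw
  units, so that is what `lr_score()` consumes; no clamp is applied to
  extreme titres.

The printed tertile ranges overlap at 100 AU; `ia2a_category()` resolves
100 AU into category 2 and, because the top category is printed
"> 290", keeps 290 AU in category 2. Children above the 90th score
centile are substage 1b, the fixed thresholds (CPH > 4.0, LR > 17.1,
strict inequalities) being that cohort's 90th centile; below the 30th
centile is 1a_low, between the two 1a_mid. `assign_substage()` exposes
both a fixed-threshold mode and a cohort-centile mode (type-7 quantiles,
i.e. linear interpolation of order statistics); ties sitting exactly on a
centile bound stay below the strict cut, so a degenerate all-equal cohort
is entirely 1a_mid. There is no published fixed 30th-centile threshold,
so that split always comes from the supplied distribution.
`longitudinal_rescore()` applies first-crossing semantics over follow-up
visits: the earliest visit whose recomputed CPH score exceeds the
threshold defines the crossing time, even if later visits fall back
below.

Note one internal tension in the published numbers: the multivariable
hazard ratio per IA-2A category is reported as 2.04, while the score
weight 0.662 corresponds to exp(0.662) = 1.94. The score formula is
treated as authoritative throughout.

## Survival machinery

`km_fit()` wraps `survival::survfit()` (product-limit estimate, Efron
convention irrelevant here since no covariates), adds the explicit
Greenwood variance, and uses log(−log) 95% intervals so bounds respect
[0, 1]; the transform is a package choice, standard but not stated in the
source material. Ties between events and censorings at the same time are
resolved events-first. Risks are read off the last step at or before the
requested time; requests beyond follow-up return the last step flagged
`extrapolated`. `annualised_risk()` is the deterministic conversion
`1 − sqrt(1 − R2)`. Group comparison uses the unweighted logrank test
(`survival::survdiff`).

## Model refitting

`univariable_screen()` fits one Cox model per candidate (Efron ties),
entering variables at two-sided p < 0.05; `multivariable_select()` then
removes, one variable at a time, the largest p ≥ 0.05, refitting after
each removal — the published procedure says only that variables "remained
significant", so largest-p-first backward elimination is the package's
interpretation, with exact-tie breaks by pre-declared candidate order and
collinear columns dropped with a warning. The binary-outcome route
(`lr_importance_fit()`) restricts to children with a defined 2-year
outcome (followed ≥ 2 years, or progressing within 2 years — the rule is
exact and tested), fits an elastic net (α = 0.5, penalty by 10-fold CV)
and a 500-tree random forest, and intersects the two top-k rankings with
k equal to the number of non-zero penalised coefficients. Permutation
importance is used for the forest: impurity importance is biased against
low-cardinality predictors, and the IA-2A ordinal (4 levels) competes
here against five mutually correlated continuous glucose measurements.
No class rebalancing is applied by default; the outcome imbalance
(roughly 1:10) is mild enough for both routes at the sizes used. IA-2A
enters the candidate set as the 0–3 ordinal (the encoding the score
uses); the raw titre can be supplied as an alternative column.

## The synthetic-cohort generator

The generator is first-class, tested code; it defines the study
conditions every downstream check runs under. What it emulates:

* **Screening layer.** Each of `n_screened` children (default 154,462) is
  confirmed multi-autoantibody positive with probability 0.0029; staged
  children split 293/364, 30/364, 41/364 into stage 1/2/3 at the first
  OGTT. Autoantibody panels (IAA, GADA, IA-2A, ZnT8A) are drawn
  marginally (defaults 0.50/0.80/0.64/0.50) conditioned on ≥ 2 positives.
* **Covariates.** (HbA1c, five OGTT glucoses, log IA-2A titre, BMI SDS)
  are multivariate normal with stage-specific means, inter-glucose
  correlation 0.45 and HbA1c–glucose correlation 0.25, truncated at
  physiologic floors, then rejection-sampled until the staging classifier
  agrees with the assigned stage label (so a "stage 1" child really is
  normoglycaemic). No joint covariate distribution is published; these
  are calibration choices, and the IA-2A log-titre scale (meanlog ≈
  log 90, sdlog 1.6) was chosen so positive titres spread across the
  three published tertile bands.
* **Progression.** Event times are exponential with hazard
  `baseline_rate · exp(lp)`, where `lp` is the published CPH linear
  predictor evaluated at the child's covariates — the printed score is
  literally the generator truth. Exponential (rather than Weibull) is the
  default because no baseline hazard shape is published and the
  exponential admits closed-form checks (`1 − exp(−rt)`); censoring is
  the minimum of an independent exponential dropout (default 0.25/year,
  giving a median follow-up near 2.8 years) and an administrative horizon
  (6 years). The baseline rate (0.032/year) and the stage 2 covariate
  shift were calibrated once so the stage 1 stratum shows ≈ 8% and the
  stage 2 stratum ≈ 50% 2-year risk — calibration constants matching the
  published magnitudes, not claims.
* **Visits.** Monitoring visits are spaced uniformly in 2–6 months
  (configurable), strictly before the event/censoring time, with a
  baseline visit at time zero; progressors drift upward in HbA1c
  (0.3%/year) and OGTT90 (15 mg/dl/year) plus measurement noise.

What it does **not** emulate: assay chemistry, age-dependent incidence,
seroconversion dynamics, the 22% of positive children never staged,
informative dropout, or a real genetic risk score (GRS is a unit-variance
scalar with no effect on the simulated hazard). Consequently, passing
tests demonstrate that the pipeline's statistics are correct under a
proportional-hazards world with the published score as truth — they are
parameter-recovery and calibration checks, not evidence about any real
cohort.

Reproducibility: a single master seed is split into fixed sub-streams
(offsets 1–4 for population, progression, visits and direct staged
draws), so each operation is independently reproducible and a fixed seed
yields a bit-identical cohort.

## Trial economics

`sample_size()` implements two standard methods: the two-proportion
normal-approximation formula on control risk vs control·(1 − effect), and
an event-count route `4(z_{α/2}+z_β)²/ln²(HR)` with the hazard ratio
implied by the two 2-year risks, both inflated by 1/(1 − dropout) and
rounded up to an even total. The published enrolment figure of 154
children has no stated derivation and neither standard formula need
reproduce it, so downstream recruitment arithmetic takes the enrolment
target as an input. `screening_requirement()` and `cost_and_yield()`
carry money in integer cents and apply the reporting roundings (nearest
10,000 children screened, nearest €100 per identified child, nearest
child for yields) only at the end.

## Numerical and testing choices

Problem sizes in the test-suite and acceptance runs were chosen as the
smallest that make the statistical assertions sharp: 50,000 staged
children for Cox coefficient recovery within 10% relative error (the
cohort yields roughly 5,000 events), 10,000+ for Kaplan–Meier
calibration within ±2 percentage points, 12,000 for the centile-mode
substaging fraction, and 2,000 bootstrap replicates by default (the
headline bootstrap of 100,000 replicates is available by argument).
Quantile estimation everywhere is R's type 7. Degenerate inputs error
loudly and early: non-PSD covariance, probabilities outside [0, 1],
missing OGTT/HbA1c fields (named in the message), empty score
collections, single-group logrank, all-one-class outcomes.

## Known limitations

* The generator's covariate distributions are calibration choices; any
  conclusion sensitive to, say, the HbA1c population SD (0.30%) should be
  re-run across plausible values.
* Progression from stage 1 to stage 2 during follow-up is not modelled as
  a state change; risk strata are defined at baseline (pooled analyses
  can be formed by the caller, as `analysis/04_progression_risk.R` does
  for the high-risk stratum).
* The LR-form score is fitted and evaluated on the binary 2-year outcome
  only; no time-varying covariate machinery is provided.
* Costs are a single per-screened-child constant; no health-economic
  offsets (ketoacidosis prevention, insulin-therapy delay) are modelled.
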