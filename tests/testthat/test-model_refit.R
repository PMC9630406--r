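test_that("the 2-year outcome restriction rule is exact", {
  co <- data.frame(
    child_id = sprintf("F%02d", 1:6),
    event_time_years = c(2.5, 1.0, 1.0, 2.0, 1.9, NA),
    event = c(FALSE, TRUE, FALSE, FALSE, FALSE, NA))
  r <- restrict_to_outcome(co, horizon = 2)
  # kept: followed >= 2y (rows 1, 4) or event within 2y (row 2);
  # dropped: censored before 2y without event (rows 3, 5), unknown (row 6)
  expect_setequal(r$child_id, c("F01", "F02", "F04"))
  expect_equal(r$outcome_2y[order(r$child_id)], c(FALSE, TRUE, FALSE))
})

test_that("univariable screen flags true predictors and skips degenerates", {
  cfg <- cohort_config(seed = 314L)
  co <- simulate_progression(simulate_staged_cohort(5000, cfg), cfg)
  co <- co[co$stage_at_staging %in% 1:2, ]
  co$constant <- 1
  spec <- fit_spec(candidate_variables = c("hba1c_pct", "glucose_90",
                                           "ia2a_cat", "grs", "constant"))
  scr <- univariable_screen(co, spec)
  # generator-truth predictors must enter at n ~ 4,000
  expect_true(all(scr$entered[scr$variable %in%
                                c("hba1c_pct", "glucose_90", "ia2a_cat")]))
  expect_true(all(scr$hr[!scr$skipped] > 0))
  expect_true(scr$skipped[scr$variable == "constant"])
  expect_match(scr$reason[scr$variable == "constant"], "constant")
  # GRS is independent of the simulated hazard
  expect_false(scr$entered[scr$variable == "grs"] &&
                 scr$p[scr$variable == "grs"] < 1e-4)
  expect_error(univariable_screen(transform(co, event = FALSE), spec),
               "no events")
})

test_that("null variables enter the univariable screen at about the
           nominal 5% rate", {
  set.seed(77)
  hits <- 0L; reps <- 120
  for (i in seq_len(reps)) {
    n <- 120
    t <- rexp(n, 0.3); e <- rep(TRUE, n)
    co <- data.frame(event_time_years = t, event = e, noise = rnorm(n))
    scr <- univariable_screen(co, fit_spec(candidate_variables = "noise"))
    hits <- hits + scr$entered[1]
  }
  # binomial(120, 0.05): mean 6, sd 2.4 -> accept within ~4 sd
  expect_lt(abs(hits - reps * 0.05), 10)
})

test_that("backward elimination retains the generator-truth model", {
  cfg <- cohort_config(seed = 2718L)
  co <- simulate_progression(simulate_staged_cohort(20000, cfg), cfg)
  co <- co[co$stage_at_staging %in% 1:2, ]
  spec <- fit_spec()
  scr <- univariable_screen(co, spec)
  entered <- scr$variable[which(scr$entered)]
  fit <- multivariable_select(co, entered, spec)
  expect_true(all(c("hba1c_pct", "glucose_90", "ia2a_cat") %in% fit$selected))
  truth <- c(hba1c_pct = 1.125, glucose_90 = 0.0195, ia2a_cat = 0.662)
  est <- fit$coefficients[names(truth)]
  expect_lt(max(abs(est - truth) / truth), 0.10)
  # eliminated variables all had p >= alpha at their removal step
  expect_true(all(!names(truth) %in% fit$eliminated))
})

test_that("multivariable fit handles collinearity and single variables", {
  cfg <- cohort_config(seed = 31L)
  co <- simulate_progression(simulate_staged_cohort(2000, cfg), cfg)
  co <- co[co$stage_at_staging %in% 1:2, ]
  co$hba1c_twin <- co$hba1c_pct   # perfectly collinear
  expect_warning(
    fit <- multivariable_select(co, c("hba1c_pct", "hba1c_twin"), fit_spec()),
    "collinear")
  expect_false("hba1c_twin" %in% fit$selected)
  # single entered variable reduces to the univariable fit
  single <- multivariable_select(co, "glucose_90", fit_spec())
  uni <- univariable_screen(co, fit_spec(candidate_variables = "glucose_90"))
  expect_equal(unname(single$hr_table$hr), uni$hr, tolerance = 1e-8)
})

test_that("penalised LR and forest importance recover the truth variables", {
  # the binary-outcome model is built on the stage 1 cohort, as the score
  # derivation prescribes
  cfg <- cohort_config(seed = 42L)
  co <- simulate_progression(simulate_staged_cohort(9000, cfg), cfg)
  co <- co[co$stage_at_staging == 1L, ]
  spec <- fit_spec(seed = 5L)
  fit <- lr_importance_fit(co, spec)
  expect_true(fit$stable)
  expect_true(all(c("hba1c_pct", "glucose_90", "ia2a_cat") %in% fit$selected))
  # coefficients exist for intercept + selected variables
  expect_equal(length(fit$lr_coefficients), length(fit$selected) + 1)
  # determinism under the fit_spec seed
  fit2 <- lr_importance_fit(co, spec)
  expect_identical(fit$selected, fit2$selected)
  expect_equal(fit$lr_coefficients, fit2$lr_coefficients)
  # all-one-class outcome errors
  co2 <- co; co2$event <- FALSE
  expect_error(lr_importance_fit(co2, spec), "single-class")
})
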