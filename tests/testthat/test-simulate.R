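test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(prevalence_multi_aab = 1.2), "probabilities")
  expect_error(cohort_config(stage_split = c(0.5, 0.2, 0.2)), "sum to 1")
  badR <- diag(8); badR[1, 2] <- 0.9   # asymmetric
  expect_error(cohort_config(covariate_corr = badR), "symmetric")
  badR <- matrix(0.99, 8, 8); diag(badR) <- 1; badR[1, 2] <- badR[2, 1] <- -0.99
  expect_error(cohort_config(covariate_corr = badR), "semi-definite")
})

test_that("screened population has binomial multi-autoantibody counts", {
  cfg <- cohort_config(n_screened = 154462, seed = 99L)
  pop <- simulate_screened_population(cfg)
  expect_equal(nrow(pop), 154462)
  n_multi <- sum(pop$multi_aab)
  mu <- 154462 * 0.0029
  sdv <- sqrt(154462 * 0.0029 * (1 - 0.0029))
  expect_lt(abs(n_multi - mu), 3 * sdv)
  # multi-aab children carry >= 2 confirmed autoantibodies and covariates
  m <- pop[pop$multi_aab, ]
  expect_true(all(m$iaa_pos + m$gada_pos + m$ia2a_pos + m$znt8a_pos >= 2))
  expect_true(all(is.finite(m$hba1c_pct)))
  expect_true(all(m$ia2a_titre >= 0))
  expect_true(all(m$ia2a_titre[!m$ia2a_pos] == 0))
  # negative-screen children have no metabolic record
  expect_true(all(is.na(pop$hba1c_pct[!pop$multi_aab])))
})

test_that("degenerate population sizes behave", {
  expect_equal(nrow(simulate_screened_population(
    cohort_config(n_screened = 0))), 0)
  pop <- simulate_screened_population(
    cohort_config(n_screened = 500, prevalence_multi_aab = 0))
  expect_equal(sum(pop$multi_aab), 0)
})

test_that("fixed seed gives a bit-identical cohort", {
  cfg <- test_config()
  a <- simulate_progression(simulate_staged_cohort(300, cfg), cfg)
  b <- simulate_progression(simulate_staged_cohort(300, cfg), cfg)
  expect_identical(a, b)
  va <- simulate_followup_visits(a, cfg)
  vb <- simulate_followup_visits(b, cfg)
  expect_identical(va, vb)
})

test_that("simulated covariates are consistent with the assigned stage", {
  cfg <- test_config()
  co <- simulate_staged_cohort(400, cfg)
  expect_equal(stage_cohort(co, confirmed = TRUE), co$stage_at_staging)
  prop <- prop.table(table(factor(co$stage_at_staging, 1:3)))
  expect_lt(max(abs(as.numeric(prop) - unname(cfg$stage_split))), 0.05)
})

test_that("event times follow the configured exponential law", {
  # zero coefficients, no censoring: mean event time -> 1/rate
  cfg <- cohort_config(true_log_hazard_coeffs = c(hba1c = 0, ogtt90 = 0,
                                                  ia2a_cat = 0),
                       baseline_hazard_rate = 0.5,
                       dropout_hazard = 0, followup_years_max = Inf,
                       seed = 123L)
  co <- simulate_progression(simulate_staged_cohort(4000, cfg), cfg)
  s12 <- co[co$stage_at_staging %in% 1:2, ]
  expect_true(all(s12$event))
  expect_equal(mean(s12$event_time_years), 2, tolerance = 0.1)
  # doubling the hazard halves the median event time
  cfg2 <- cohort_config(true_log_hazard_coeffs = c(hba1c = 0, ogtt90 = 0,
                                                   ia2a_cat = 0),
                        baseline_hazard_rate = 1.0,
                        dropout_hazard = 0, followup_years_max = Inf,
                        seed = 123L)
  co2 <- simulate_progression(simulate_staged_cohort(4000, cfg2), cfg2)
  s12b <- co2[co2$stage_at_staging %in% 1:2, ]
  expect_equal(median(s12$event_time_years) / median(s12b$event_time_years),
               2, tolerance = 0.15)
  # at the centering covariate values the hazard is the baseline rate:
  # the simulated KM risk matches the closed form 1 - exp(-r t)
  r2 <- risk_at(km_fit(s12$event_time_years, s12$event), 2)$risk
  expect_equal(r2, 1 - exp(-0.5 * 2), tolerance = 0.03)
})

test_that("follow-up visits respect spacing, drift and noise settings", {
  cfg <- test_config(visit_interval_months = c(3, 3),
                     visit_drift = c(hba1c = 0, ogtt90 = 0),
                     visit_noise = c(hba1c = 0, ogtt90 = 0, log_titre = 0))
  co <- simulate_progression(simulate_staged_cohort(50, cfg), cfg)
  co <- co[co$stage_at_staging %in% 1:2, ][1, ]
  co$event_time_years <- 1.0; co$event <- TRUE
  v <- simulate_followup_visits(co, cfg)
  # exact 3-month spacing: baseline plus 0.25/0.50/0.75 = 4 visits before 1.0
  expect_equal(nrow(v), 4)
  expect_equal(v$time_years, c(0, 0.25, 0.5, 0.75))
  # zero drift and noise: visit values equal baseline
  expect_true(all(v$hba1c_pct == co$hba1c_pct))
  expect_true(all(v$glucose_90 == co$glucose_90))
  expect_true(all(v$ia2a_titre == co$ia2a_titre))
  # no follow-up window -> no visits
  co$event_time_years <- 0
  expect_equal(nrow(simulate_followup_visits(co, cfg)), 0)
  # progressors drift upward when drift is on
  cfg2 <- test_config(visit_interval_months = c(3, 3),
                      visit_noise = c(hba1c = 0, ogtt90 = 0, log_titre = 0))
  co$event_time_years <- 2.0
  v2 <- simulate_followup_visits(co, cfg2)
  expect_true(all(diff(v2$hba1c_pct) > 0))
  expect_true(all(diff(v2$glucose_90) > 0))
})
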