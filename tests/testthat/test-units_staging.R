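test_that("glucose and HbA1c unit conversions match paired clinical values", {
  # diabetic 2 h threshold: 200 mg/dl is quoted as 11.1 mmol/l
  expect_equal(round(glucose_mgdl_to_mmoll(200), 1), 11.1)
  # dysglycaemia band endpoints agree at 1 d.p.
  expect_equal(round(glucose_mgdl_to_mmoll(c(110, 125, 140, 199)), 1),
               c(6.1, 6.9, 7.8, 11.0))
  # HbA1c 6.5% is reported as 48 mmol/mol after integer rounding
  expect_equal(round(hba1c_pct_to_mmolmol(6.5)), 48)
  expect_equal(round(hba1c_pct_to_mmolmol(c(5.7, 6.4)) ), c(39, 46))
  expect_equal(glucose_mgdl_to_mmoll(0), 0)
  # round trips
  v <- c(0, 50, 107.6, 200, 345)
  expect_equal(glucose_mmoll_to_mgdl(glucose_mgdl_to_mmoll(v)), v,
               tolerance = 1e-9)
  h <- c(4.5, 5.233, 6.5, 9)
  expect_equal(hba1c_mmolmol_to_pct(hba1c_pct_to_mmolmol(h)), h,
               tolerance = 1e-9)
  expect_error(glucose_mgdl_to_mmoll(-1), "negative")
  expect_error(hba1c_pct_to_mmolmol(-0.1), "negative")
})

test_that("staging follows the 2015 consensus rules", {
  # impaired fasting glucose -> stage 2
  r <- classify_stage(normal_ogtt(g0 = 120, g120 = 150), hba1c_pct = 5.4)
  expect_equal(r$stage, 2L)
  expect_true("impaired_fasting_glucose" %in% r$criteria_met)
  # fully normal profile -> stage 1, no criteria fired
  r <- classify_stage(normal_ogtt(g0 = 90, g120 = 120), hba1c_pct = 5.2)
  expect_equal(r$stage, 1L)
  expect_length(r$criteria_met, 0)
  # intermediate OGTT value >= 200 is a stage 2 criterion
  r <- classify_stage(normal_ogtt(g60 = 205, g120 = 130), hba1c_pct = 5.2)
  expect_equal(r$stage, 2L)
  expect_true("intermediate_glucose_ge_200" %in% r$criteria_met)
  # diabetic thresholds take precedence over dysglycaemia
  r <- classify_stage(normal_ogtt(g0 = 130, g120 = 150), hba1c_pct = 5.4)
  expect_equal(r$stage, 3L)
  expect_true(r$requires_confirmation)
  r <- classify_stage(normal_ogtt(g0 = 130, g120 = 150), hba1c_pct = 5.4,
                      confirmed = TRUE)
  expect_false(r$requires_confirmation)
  # HbA1c above 48 mmol/mol alone defines stage 3
  r <- classify_stage(normal_ogtt(), hba1c_pct = 7.0)
  expect_equal(r$stage, 3L)
  # symptomatic child with random glucose > 200 needs no confirmation
  r <- classify_stage(normal_ogtt(), hba1c_pct = 5.2, symptoms = TRUE,
                      random_glucose_mgdl = 250)
  expect_equal(r$stage, 3L)
  expect_false(r$requires_confirmation)
})

test_that("revised ADA criteria widen the stage 2 definition", {
  # fasting 105 mg/dl: normal under 2015, impaired under the revision
  expect_equal(classify_stage(normal_ogtt(g0 = 105, g120 = 120),
                              hba1c_pct = 5.2)$stage, 1L)
  expect_equal(classify_stage(normal_ogtt(g0 = 105, g120 = 120),
                              hba1c_pct = 5.2,
                              criteria_set = "ada_revised")$stage, 2L)
  # HbA1c 39-47 mmol/mol band fires only in the revision
  expect_equal(classify_stage(normal_ogtt(), hba1c_pct = 6.0)$stage, 1L)
  r <- classify_stage(normal_ogtt(), hba1c_pct = 6.0,
                      criteria_set = "ada_revised")
  expect_equal(r$stage, 2L)
  expect_true("hba1c_39_47_mmolmol" %in% r$criteria_met)
  # >= 10% relative HbA1c rise from the earliest value
  r <- classify_stage(normal_ogtt(), hba1c_pct = 5.6,
                      criteria_set = "ada_revised", earliest_hba1c_pct = 5.0)
  expect_true("hba1c_rise_ge_10pct" %in% r$criteria_met)
  expect_equal(classify_stage(normal_ogtt(), hba1c_pct = 5.4,
                              criteria_set = "ada_revised",
                              earliest_hba1c_pct = 5.0)$stage, 1L)
})

test_that("staging errors name the missing measurement", {
  expect_error(classify_stage(c(90, 140, NA, 107, 120), hba1c_pct = 5.2),
               "ogtt_glucose_mgdl")
  expect_error(classify_stage(normal_ogtt(), criteria_set = "ada_revised"),
               "hba1c_pct")
  expect_error(classify_stage(normal_ogtt(g0 = -5), hba1c_pct = 5.2),
               "positive")
})

test_that("staging is monotone in glucose and exhaustive", {
  set.seed(91)
  for (i in 1:60) {
    g <- normal_ogtt(runif(1, 60, 140), runif(1, 80, 230), runif(1, 80, 230),
                     runif(1, 80, 230), runif(1, 80, 230))
    h <- runif(1, 4.5, 7.2)
    for (crit in c("consensus2015", "ada_revised")) {
      base <- classify_stage(g, hba1c_pct = h, criteria_set = crit)
      expect_true(base$stage %in% 1:3)  # exactly one stage always assigned
      k <- sample(5, 1)
      g2 <- g; g2[k] <- g2[k] + runif(1, 0, 80)
      expect_gte(classify_stage(g2, hba1c_pct = h,
                                criteria_set = crit)$stage, base$stage)
    }
  }
})

test_that("staging is invariant to the input unit system", {
  set.seed(17)
  for (i in 1:40) {
    g <- normal_ogtt(runif(1, 70, 135), runif(1, 90, 220), runif(1, 90, 220),
                     runif(1, 90, 220), runif(1, 90, 220))
    h <- runif(1, 4.8, 7.0)
    g_back <- glucose_mmoll_to_mgdl(glucose_mgdl_to_mmoll(g))
    h_back <- hba1c_mmolmol_to_pct(hba1c_pct_to_mmolmol(h))
    for (crit in c("consensus2015", "ada_revised")) {
      expect_equal(
        classify_stage(g_back, hba1c_pct = h_back, criteria_set = crit)$stage,
        classify_stage(g, hba1c_pct = h, criteria_set = crit)$stage)
    }
  }
})

test_that("weight status uses inclusive 1-2 SDS overweight band", {
  expect_equal(classify_weight_status(c(0, 1.5, 2.0, 1.0, 2.5, -1.2)),
               c("normal", "overweight", "overweight", "overweight",
                 "obese", "normal"))
  expect_error(classify_weight_status(NaN), "finite")
})
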