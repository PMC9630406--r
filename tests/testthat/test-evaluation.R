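test_that("threshold diagnostics reproduce the printed likelihood ratios", {
  # counts engineered to sensitivity 55%, specificity 93%
  scores <- c(rep(5, 11), rep(1, 9),    # 20 progressors: 11 above threshold
              rep(5, 7), rep(1, 93))    # 100 non-progressors: 7 above
  outcome <- c(rep(TRUE, 20), rep(FALSE, 100))
  d <- threshold_diagnostics(scores, outcome, threshold = 4)
  expect_equal(c(d$tp, d$fn, d$fp, d$tn), c(11, 9, 7, 93))
  expect_equal(d$sensitivity, 0.55)
  expect_equal(d$specificity, 0.93)
  expect_equal(round(d$lr_positive, 1), 7.9)
  expect_equal(round(d$lr_negative, 1), 0.5)
  # the two diagnostic OR forms agree exactly on unrounded inputs
  expect_equal(d$diagnostic_or, d$diagnostic_or_counts, tolerance = 1e-12)
  expect_equal(d$diagnostic_or, (11 * 93) / (7 * 9), tolerance = 1e-12)
})

test_that("degenerate classifications give NA metrics, not infinities", {
  # perfect score
  d <- threshold_diagnostics(c(10, 10, 1, 1), c(TRUE, TRUE, FALSE, FALSE), 5)
  expect_equal(c(d$sensitivity, d$specificity, d$ppv), c(1, 1, 1))
  expect_true(is.na(d$lr_positive))   # 1 - spec = 0: undefined, not Inf
  # no positives at all
  d <- threshold_diagnostics(c(1, 1), c(TRUE, FALSE), 5)
  expect_true(is.na(d$ppv))
  expect_false(any(vapply(d[c("lr_positive", "lr_negative",
                              "diagnostic_or")], is.infinite, logical(1))))
})

test_that("decile curve: sensitivities and bins behave on exact fixtures", {
  # everyone progresses within the horizon: sensitivity at any edge is the
  # fraction of the cohort scoring above it
  n <- 200
  set.seed(4)
  sc <- runif(n)
  cur <- decile_curve(sc, times = rep(1, n), events = rep(TRUE, n),
                      horizon = 2)
  for (i in seq_len(nrow(cur$sensitivity))) {
    thr <- cur$sensitivity$threshold[i]
    expect_equal(cur$sensitivity$sensitivity[i], mean(sc > thr))
  }
  expect_equal(sum(cur$bins$n), n)   # bins partition the cohort
  # sensitivity is non-increasing in the threshold centile
  expect_true(all(diff(cur$sensitivity$sensitivity) <= 0))
  # <10 distinct scores falls back to coarser bins with a warning
  expect_warning(decile_curve(rep(c(1, 2), 50), rep(1, 100),
                              rep(TRUE, 100)), "coarser")
})

test_that("decile risks are flat under a null score and rise under truth", {
  cfg <- cohort_config(seed = 5L)
  co <- simulate_progression(simulate_staged_cohort(10000, cfg), cfg)
  co <- co[co$stage_at_staging == 1L, ]
  overall <- risk_at(km_fit(co$event_time_years, co$event), 2)$risk
  # null score: per-bin risks scatter around the overall risk
  set.seed(6)
  null_cur <- decile_curve(runif(nrow(co)), co$event_time_years, co$event)
  expect_lt(max(abs(null_cur$bins$risk - overall)), 0.05)
  # true-score ordering: risk in the top decile far exceeds the bottom,
  # and risks trend upward across bins
  sc <- cph_score(co$hba1c_pct, co$glucose_90, co$ia2a_cat)
  cur <- decile_curve(sc, co$event_time_years, co$event)
  risks <- cur$bins$risk
  expect_gt(risks[10], overall)
  expect_gt(risks[10], risks[1] + 0.1)
  expect_gt(cor(seq_along(risks), risks, method = "spearman"), 0.8)
  # the 90th-centile decile edge reproduces the fixed-threshold sensitivity
  edge <- cur$sensitivity$threshold[cur$sensitivity$centile == 90]
  prog <- co$event & co$event_time_years <= 2
  expect_equal(
    cur$sensitivity$sensitivity[cur$sensitivity$centile == 90],
    sum(prog & sc > edge) / sum(prog))
})

test_that("bootstrap percentile intervals are calibrated and reproducible", {
  # constant statistic: zero-width interval
  b <- bootstrap_ci(function(d) 1, data.frame(x = 1:50), replicates = 200,
                    seed = 2L)
  expect_equal(b$ci_low, b$ci_high)
  # mean of N(0,1), n = 200: CI width ~ 2 * 1.96 / sqrt(200)
  set.seed(11)
  x <- rnorm(200)
  b <- bootstrap_ci(mean, x, replicates = 4000, seed = 3L)
  expect_equal(b$ci_high - b$ci_low, 2 * 1.96 / sqrt(200), tolerance = 0.15)
  # identical seeds give identical intervals
  b2 <- bootstrap_ci(mean, x, replicates = 4000, seed = 3L)
  expect_identical(b[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_error(bootstrap_ci(mean, x, replicates = 50), "100")
  # mostly-undefined statistics abort with a diagnostic
  expect_error(
    bootstrap_ci(function(d) NA_real_, x, replicates = 200, seed = 4L),
    "undefined")
})
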