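# fixture builders shared across test files

# a complete, normoglycaemic OGTT profile (mg/dl at 0/30/60/90/120 min)
normal_ogtt <- function(g0 = 90, g30 = 140, g60 = 125, g90 = 107, g120 = 120) {
  c(g0, g30, g60, g90, g120)
}

# a tiny hand-checkable staged cohort with follow-up columns
tiny_followup_cohort <- function() {
  data.frame(
    child_id = sprintf("K%02d", 1:6),
    hba1c_pct = c(5.2, 5.4, 5.9, 5.1, 6.0, 5.3),
    glucose_90 = c(100, 120, 160, 95, 170, 110),
    ia2a_titre = c(0, 50, 350, 0, 400, 120),
    event_time_years = c(3.0, 1.5, 0.8, 2.5, 0.4, 2.2),
    event = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# small config for fast simulation tests
test_config <- function(...) {
  cohort_config(n_screened = 2000, seed = 20240101L, ...)
}
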