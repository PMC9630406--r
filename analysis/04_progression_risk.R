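#!/usr/bin/env Rscript
# Kaplan-Meier progression risk by baseline stage and by score substage:
# 2-year risks with log(-log) CIs, logrank comparisons, annualised-risk
# conversions, and a number-at-risk table.

suppressPackageStartupMessages(library(t1dstage))

staged <- read_cohort("results/staged_cohort.csv")
s1 <- utils::read.csv("results/stage1_scores.csv")

followed <- staged[staged$stage_at_staging %in% 1:2, ]

report_risk <- function(label, times, events) {
  r <- risk_at(km_fit(times, events), 2)
  cat(sprintf("%-28s n=%5d  2y risk %5.1f%% (95%% CI %.1f, %.1f)  annualised %4.1f%%\n",
              label, length(times), 100 * r$risk, 100 * r$ci_low,
              100 * r$ci_high, 100 * annualised_risk(min(r$risk, 0.999))))
  r
}

for (st in 1:2) {
  idx <- followed$stage_at_staging == st
  report_risk(paste("stage", st), followed$event_time_years[idx],
              followed$event[idx])
}
lr <- logrank(followed$event_time_years, followed$event,
              followed$stage_at_staging)
cat(sprintf("logrank stage 1 vs 2: chisq %.1f, p %.2g\n", lr$chisq, lr$p))

# substage strata within stage 1, plus the pooled high-risk stratum
for (ss in c("1a_low", "1a_mid", "1b")) {
  idx <- s1$substage_fixed == ss
  if (sum(idx) > 2) {
    report_risk(paste("stage", ss), s1$event_time_years[idx], s1$event[idx])
  }
}
hi <- rbind(
  s1[s1$substage_fixed == "1b", c("event_time_years", "event")],
  followed[followed$stage_at_staging == 2, c("event_time_years", "event")])
invisible(report_risk("stage 1b or stage 2", hi$event_time_years, hi$event))

# per-stage survival curve with numbers at risk on a yearly grid
curves <- do.call(rbind, lapply(1:2, function(st) {
  idx <- followed$stage_at_staging == st
  f <- km_fit(followed$event_time_years[idx], followed$event[idx])
  data.frame(stage = st, time = f$time, surv = f$surv,
             ci_low = f$ci_low, ci_high = f$ci_high, n_risk = f$n_risk)
}))
utils::write.csv(curves, "results/km_curves.csv", row.names = FALSE)

at_risk <- do.call(rbind, lapply(1:2, function(st) {
  idx <- followed$stage_at_staging == st
  t <- followed$event_time_years[idx]
  data.frame(stage = st, year = 0:5,
             n_at_risk = vapply(0:5, function(y) sum(t >= y), numeric(1)))
}))
utils::write.csv(at_risk, "results/number_at_risk.csv", row.names = FALSE)
cat("wrote results/km_curves.csv, results/number_at_risk.csv\n")
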