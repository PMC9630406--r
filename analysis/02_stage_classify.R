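#!/usr/bin/env Rscript
# Re-classify the staged cohort under the 2015 consensus criteria and the
# revised ADA criteria, and tabulate how the revision reshuffles stage 1
# and stage 2 (the revised fasting band 100-125 mg/dl and the HbA1c
# 39-47 mmol/mol rule move normoglycaemic children into stage 2).

suppressPackageStartupMessages(library(t1dstage))

staged <- read_cohort("results/staged_cohort.csv")

st2015 <- stage_cohort(staged, criteria_set = "consensus2015", confirmed = TRUE)
stada <- stage_cohort(staged, criteria_set = "ada_revised", confirmed = TRUE)

tab <- table(consensus2015 = st2015, ada_revised = stada)
print(tab)
cat(sprintf("revised criteria move %d of %d stage 1 children to stage 2\n",
            sum(st2015 == 1 & stada == 2), sum(st2015 == 1)))

weight <- classify_weight_status(staged$bmi_sds)
cat("weight status:", paste(names(table(weight)), table(weight),
                            collapse = ", "), "\n")

out <- data.frame(child_id = staged$child_id, stage_consensus2015 = st2015,
                  stage_ada_revised = stada, weight_status = weight)
utils::write.csv(out, "results/staging_classification.csv", row.names = FALSE)
cat("wrote results/staging_classification.csv\n")
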