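#!/usr/bin/env Rscript
# Step 1 — simulate the study cohorts.
#
# Generates a development cohort and a temporally-shifted validation cohort
# with the documented ED marginals (mean age ~62, 45% female, ~11%
# bacteremia prevalence, <3% missingness confined to vital signs) and a
# known logistic generative risk, then writes them as CSV + JSONL under
# results/data/.

library(bacterisk)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

dev <- generate_cohort(cohort_spec(n_cases = 15000, seed = 101))
val <- generate_cohort(cohort_spec(n_cases = 8000, target_prevalence = 0.103,
                                   seed = 102))

write_cohort(dev, "results/data/dev_cohort.csv", "results/data/dev_notes.jsonl")
write_cohort(val, "results/data/val_cohort.csv", "results/data/val_notes.jsonl")

summarize <- function(co, name) {
  cat(sprintf(
    "%s: n=%d  age %.1f (%.1f)  female %.1f%%  bacteremia %.1f%%  missing vitals %.2f%%\n",
    name, nrow(co), mean(co$age), sd(co$age), 100 * mean(co$sex == "female"),
    100 * mean(co$label),
    100 * mean(is.na(co[, c("sbp", "dbp", "hr", "rr", "bt")]))))
}
summarize(dev, "development")
summarize(val, "validation ")
cat(sprintf("Bayes-optimal AUC (development): %.3f\n",
            roc_auc_delong(dev$true_risk, dev$label)$auc))
cat("wrote results/data/{dev,val}_{cohort.csv,notes.jsonl}\n")
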