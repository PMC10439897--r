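#!/usr/bin/env Rscript
# Step 3 — Phase 2: simulated reader study.
#
# Samples 1,000 validation cases into 10 sets of 100, each reviewed by two
# simulated readers before and after seeing the AI prediction and its 95%
# interval, then compares pre- vs post-AI performance with the
# Obuchowski-Rockette MRMC test, inter-reader weighted kappa, the paired
# confidence t-test, rating-transition counts, and the dual-uncertainty
# subgroup analyses. Reports land in results/phase2/.

library(bacterisk)

val <- read_cohort("results/data/val_cohort.csv", "results/data/val_notes.jsonl")
preds <- utils::read.csv("results/phase1/predictions_full.csv",
                         stringsAsFactors = FALSE)

report <- run_phase2(val, preds, reader_params(seed = 301L),
                     n_cases = 1000L, threshold = 0.05,
                     out_dir = "results/phase2", seed = 302L)

m <- report$mrmc
cat(sprintf("AI AUC on sampled cases: %.3f\n", report$ai_auc$auc))
cat(sprintf("reader AUC pre %.3f -> post %.3f (diff %.3f, p = %.2g)\n",
            m$auc_pre, m$auc_post, m$difference, m$p_value))
cat(sprintf("weighted kappa pre %.2f -> post %.2f\n",
            report$kappa_pre, report$kappa_post))
ct <- report$confidence_test
cat(sprintf("confidence change +%.2f Likert points (paired t = %.2f, p = %.2g)\n",
            ct$mean_difference, ct$t, ct$p_value))
cat("\nsubgroup MRMC (post - pre AUC difference):\n")
for (nm in names(report$mrmc_subgroups)) {
  s <- report$mrmc_subgroups[[nm]]
  if (is.null(s)) { cat(sprintf("  %-16s skipped\n", nm)); next }
  cat(sprintf("  %-16s n=%4d  diff %+0.3f  p = %.2g\n", nm,
              attr(s, "n_cases"), s$difference, s$p_value))
}
cat("\nrating transitions (very low vs low-high):\n")
print(report$transitions)
cat("wrote results/phase2/\n")
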