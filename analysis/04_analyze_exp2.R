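#!/usr/bin/env Rscript
# Inferential analysis of the four-group additive cohort.
#
# On the surviving exp2 scores: the replication power analysis, one-way
# ANOVAs with linear contrasts over the four additive groups for the bias
# measures, the planned control-vs-full comparisons, hindsight-bias tests,
# and the per-group AIP regressions.

library(offloadr)

dir <- file.path("results", "exp2")
surv <- read_scores(file.path(dir, "surviving_scores.csv"))

cat("planned n per group (d = 0.347, one-tailed, 80% power):",
    power_n_per_group(0.347, 0.05, 0.80, "one"), "\n\n")

cat("surviving sample:", nrow(surv), "participants\n")
summary_tab <- group_summary(surv)
utils::write.csv(summary_tab, file.path(dir, "group_summary.csv"),
                 row.names = FALSE)
print(summary_tab[, c("measure", paste0(offload_groups(), "_mean"))],
      digits = 3)

stats <- experiment_stats(surv, "exp2")

cat("\n-- absolute pre-task metacognitive bias: one-way ANOVA + linear contrast --\n")
print(stats$abs_meta_bias_pre_contrast, digits = 4)
cat("\n-- absolute post-task metacognitive bias --\n")
print(stats$abs_meta_bias_post_contrast, digits = 4)
cat("\n-- signed reminder bias --\n")
print(stats$reminder_bias_contrast, digits = 4)
cat("\n-- absolute reminder bias --\n")
print(stats$abs_reminder_bias_contrast, digits = 4)

cat("\n-- planned comparisons: control vs full intervention --\n")
cat("absolute metacognitive bias: "); print(stats$abs_meta_bias_pre_g1_g4)
cat("absolute reminder bias:      "); print(stats$abs_reminder_bias_g1_g4)

cat("\n-- hindsight bias --\n")
cat("pooled: "); print(stats$hindsight$pooled)
for (g in names(stats$hindsight$per_group)) {
  cat(g, ": "); print(stats$hindsight$per_group[[g]])
}
print(stats$hindsight$anova, digits = 4)

cat("\n-- AIP ~ OIP + confidence, per group --\n")
for (g in names(stats$regression)) {
  cat(g, ": "); print(stats$regression[[g]])
}

write_stats_json(stats, file.path(dir, "stats.json"))
cat("\nstats written to", file.path(dir, "stats.json"), "\n")
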