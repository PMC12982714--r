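#!/usr/bin/env Rscript
# Inferential analysis of the two-group cohort.
#
# On the surviving exp1 scores: the planned sample size, mixed Group x Time
# ANOVAs on signed and absolute metacognitive bias, the one-tailed group
# comparisons at each timepoint, one-sample reminder-bias tests, the group
# comparison of (absolute) reminder bias, and per-group regressions of AIP
# on OIP plus confidence.

library(offloadr)

dir <- file.path("results", "exp1")
surv <- read_scores(file.path(dir, "surviving_scores.csv"))

cat("planned n per group (d = 0.39, one-tailed, 80% power):",
    power_n_per_group(0.39, 0.05, 0.80, "one"), "\n\n")

cat("surviving sample:", nrow(surv), "participants\n")
summary_tab <- group_summary(surv)
utils::write.csv(summary_tab, file.path(dir, "group_summary.csv"),
                 row.names = FALSE)
print(summary_tab, digits = 3)

stats <- experiment_stats(surv, "exp1")

cat("\n-- metacognitive bias, mixed 2x2 (Group x Time) --\n")
print(stats$meta_bias_anova, digits = 4)
cat("\n-- absolute metacognitive bias, mixed 2x2 --\n")
print(stats$abs_meta_bias_anova, digits = 4)

cat("\n-- group comparison of pre-task absolute metacognitive bias --\n")
print(stats$abs_meta_bias_pre_group)

cat("\n-- reminder bias vs zero, per group --\n")
for (g in names(stats$reminder_bias_onesample)) {
  cat(g, ": "); print(stats$reminder_bias_onesample[[g]])
}
cat("\n-- group comparison of reminder bias (one-tailed, pooled) --\n")
print(stats$reminder_bias_group)
cat("\n-- group comparison of absolute reminder bias --\n")
print(stats$abs_reminder_bias_group)

cat("\n-- AIP ~ OIP + confidence, per group --\n")
for (g in names(stats$regression)) {
  cat(g, ": "); print(stats$regression[[g]])
}

write_stats_json(stats, file.path(dir, "stats.json"))
cat("\nstats written to", file.path(dir, "stats.json"), "\n")
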