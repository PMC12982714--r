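#!/usr/bin/env Rscript
# Score both cohorts and apply the pre-registered exclusion cascade.
#
# Reads the tidy trial/participant tables written by 01_simulate.R (the
# same schema an external behavioural-platform export would use), computes
# the nine derived measures per participant, and filters through the
# six-criterion exclusion cascade (accuracy floors, counter-rational
# choice, internal > external accuracy, and the two 2.5-MAD outlier rules).

library(offloadr)

for (exp in c("exp1", "exp2")) {
  dir <- file.path("results", exp)
  trials <- read_trials(file.path(dir, "trials.csv"))
  participants <- read_participants(file.path(dir, "participants.csv"))
  records <- records_from_frames(trials, participants)
  scores <- score_cohort(records)
  write_scores(scores, file.path(dir, "scores.csv"))

  excl <- apply_exclusions(scores, trials = trials)
  utils::write.csv(excl$flags, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  write_scores(excl$survivors, file.path(dir, "surviving_scores.csv"))

  cat(sprintf("%s: scored %d participants; excluded %d\n",
              exp, nrow(scores), sum(excl$flags$excluded)))
  print(excl$counts)
  cat(sprintf("  surviving: %d\n", length(excl$surviving_ids)))
}
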