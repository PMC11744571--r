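#!/usr/bin/env Rscript
# Stage 2: score the dual-task Stroop trials (RT on correct trials, error
# rate, inverse efficiency) per cell and z-normalize against the
# pre-intervention pool.

library(brainbreaks)

trials <- read.csv("results/stroop_trials.csv")
summaries <- zscore_measures(summarize_trials(trials))
write.csv(summaries, "results/behavior_summaries.csv", row.names = FALSE)

cat("Scored", nrow(summaries), "cells from", nrow(trials), "trials\n")
dropped <- sum(summaries$undefined_rt)
cat("Cells without any correct trial (excluded downstream):", dropped, "\n")

cell_means <- aggregate(cbind(mean_rt_correct_ms, error_rate, ies_ms) ~
                          condition + timepoint, data = summaries, FUN = mean)
print(cell_means, digits = 4)

did <- function(measure) {
  cm <- tapply(summaries[[measure]], list(summaries$condition, summaries$timepoint), mean)
  c(MIC = unname((cm["MIC", "post"] - cm["MIC", "pre"]) - (cm["SIT", "post"] - cm["SIT", "pre"])),
    VIC = unname((cm["VIC", "post"] - cm["VIC", "pre"]) - (cm["SIT", "post"] - cm["SIT", "pre"])))
}
cat("\nRaw post-pre difference-in-differences vs SIT:\n")
cat("RT (ms):  "); print(round(did("mean_rt_correct_ms"), 2))
cat("z-RT:     "); print(round(did("z_rt"), 3))
cat("z-ER:     "); print(round(did("z_er"), 3))
cat("z-IES:    "); print(round(did("z_ies"), 3))
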