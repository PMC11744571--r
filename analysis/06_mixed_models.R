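#!/usr/bin/env Rscript
# Stage 6: the study's linear mixed models. For every outcome: ML-estimated
# condition x timepoint (x block) model with sex/age/BMI covariates and a
# participant random intercept, estimated-marginal-means post-pre
# difference-in-differences contrasts with FDR, and assumption diagnostics.

library(brainbreaks)

covariates <- read.csv("results/covariates.csv")
behavior <- merge(read.csv("results/behavior_summaries.csv"), covariates, by = "subject")
retina <- merge(read.csv("results/retinal_indices.csv"), covariates, by = "subject")
cd_rest <- merge(read.csv("results/causal_density_resting.csv"), covariates, by = "subject")
cd_task <- merge(read.csv("results/causal_density_task.csv"), covariates, by = "subject")

run_outcome <- function(data, outcome, include_block = FALSE, covs = c("sex", "age", "bmi")) {
  fit <- fit_lmm(lmm_spec(outcome, include_block = include_block, covariates = covs), data)
  ct <- suppressMessages(emmeans_contrasts(fit))
  chk <- check_assumptions(fit, n_boot = 200L)
  list(fit = fit, contrasts = cbind(outcome = outcome, ct),
       diag = data.frame(outcome = outcome, shapiro_p = chk$shapiro_p,
                         breusch_pagan_p = chk$breusch_pagan_p,
                         dw = chk$durbin_watson$statistic,
                         remediation = chk$remediation))
}

res <- list(
  run_outcome(behavior, "z_rt", include_block = TRUE),
  run_outcome(behavior, "z_er", include_block = TRUE),
  run_outcome(behavior, "z_ies", include_block = TRUE),
  run_outcome(retina, "crae"),
  run_outcome(retina, "crve"),
  run_outcome(retina, "avr"),
  run_outcome(cd_rest, "causal_density"),
  run_outcome(cd_task, "causal_density")
)
res[[7]]$contrasts$outcome <- "cd_resting"
res[[8]]$contrasts$outcome <- "cd_task"

contrasts <- do.call(rbind, lapply(res, `[[`, "contrasts"))
diags <- do.call(rbind, lapply(res, `[[`, "diag"))
write.csv(contrasts, "results/lmm_did_contrasts.csv", row.names = FALSE)
write.csv(diags, "results/lmm_diagnostics.csv", row.names = FALSE)

cat("Post-pre difference-in-differences contrasts (FDR within outcome family):\n")
print(contrasts[, c("outcome", "contrast", "estimate", "se", "p_fdr")],
      digits = 3, row.names = FALSE)
cat("\nAssumption diagnostics:\n")
print(diags, digits = 3, row.names = FALSE)
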