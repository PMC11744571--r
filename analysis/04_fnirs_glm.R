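#!/usr/bin/env Rscript
# Stage 4: forward-simulate task fNIRS recordings for a subsample of
# subjects, preprocess (QC, OD, MBLL, PCA), fit the canonical-HRF AR-IRLS
# GLM per ROI, and summarize group activation with FDR correction.
# A subsample keeps this stage to a couple of minutes; the estimators are
# identical at any scale.

library(brainbreaks)

n_subj <- 6L
fs <- 10.2
duration_s <- 240
active <- c(2L, 3L, 6L, 7L)  # bilateral superior/middle frontal
sched <- data.frame(onset_s = c(20, 100, 180), duration_s = 50,
                    type = c("baseline", "color_dual", "lexical_dual"))

truth <- var_ground_truth(9L, 1L, diag(0.3, 9) +
                            0.25 * (col(diag(9)) == 1 & row(diag(9)) == 3))
rows <- list()
for (cond in c("SIT", "MIC")) {
  for (subj in seq_len(n_subj)) {
    amp <- if (cond == "MIC") 1.3 else 1.0
    rec <- generate_fnirs_recording(
      truth, task_design = sched, duration_s = duration_s, fs = fs,
      seed = subj * 100L + (cond == "MIC"), active_rois = active,
      task_amplitude_um = amp
    )
    pre <- preprocess_recording(rec$intensity, filter_band = NULL,
                                pca_components = 0L)
    des <- build_design(sched, n_samples = nrow(pre$hbo), fs = fs)
    for (roi in colnames(pre$hbo)) {
      fit <- fit_ar_irls(pre$hbo[, roi] * 1e3, des, max_ar_order = 20L)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", subj), condition = cond, roi = roi,
        beta = unname(fit$beta[["color_dual"]]), ar_order = fit$ar_order,
        converged = fit$converged
      )
    }
  }
}
betas <- do.call(rbind, rows)
write.csv(betas, "results/glm_roi_betas.csv", row.names = FALSE)

grp <- group_level(betas)
write.csv(grp, "results/glm_group_activation.csv", row.names = FALSE)
cat("Fitted", nrow(betas), "ROI-level AR-IRLS GLMs;",
    sum(!betas$converged), "non-converged\n")
cat("Group-level activation (color-dual regressor), FDR-corrected:\n")
print(grp[order(grp$p_fdr), ], digits = 3, row.names = FALSE)
cat("Active ROIs (2,3,6,7) should dominate the discovery list.\n")
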