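# Parameter-recovery experiments: generate data under an effect profile and
# re-estimate the injected effects with the pipeline's own estimators. These
# back both the validation suite and the reproduction script.

#' Mediation path recovery experiment
#'
#' Generates change-score datasets under the profile's mediation paths
#' (n = profile subjects, low noise), fits the covariate-adjusted mediation
#' with the bias-corrected bootstrap, and averages the estimates over seeds.
#'
#' @param profile An [effect_profile()].
#' @param seeds Integer vector of generator seeds.
#' @param noise_sd Generator error SD.
#' @param n_boot Bootstrap resamples per fit.
#' @return List with mean `total`, `direct`, `indirect`, the per-seed
#'   estimates, and `all_ci_exclude_zero` for the indirect path.
#' @export
recover_mediation_paths <- function(profile = paper_effects(), seeds = 1:20,
                                    noise_sd = 0.1, n_boot = 10000L) {
  per_seed <- t(vapply(seeds, function(s) {
    d <- generate_mediation_dataset(profile$mediation_paths,
                                    n = profile$n_subjects,
                                    noise_sd = noise_sd, covariates = TRUE,
                                    seed = s, profile = profile)
    fit <- fit_mediation(d, covariates = TRUE, n_boot = n_boot, seed = s)
    est <- setNames(fit$paths$estimate, fit$paths$path)
    c(total = est[["c"]], direct = est[["c_prime"]],
      indirect = est[["indirect"]], excludes_zero = as.numeric(fit$significant))
  }, numeric(4L)))
  list(total = mean(per_seed[, "total"]), direct = mean(per_seed[, "direct"]),
       indirect = mean(per_seed[, "indirect"]),
       all_ci_exclude_zero = all(per_seed[, "excludes_zero"] == 1),
       per_seed = per_seed)
}

#' Behavioral contrast recovery experiment
#'
#' Generates two-condition study data (control vs moderate exercise), scores
#' and z-normalizes the Stroop trials, fits the condition x timepoint x block
#' mixed model with sex/age/BMI covariates per measure, and averages the
#' exercise-vs-control post-pre difference-in-differences contrast over
#' seeds.
#'
#' @param profile An [effect_profile()].
#' @param seeds Integer vector of generator seeds.
#' @return List with mean `z_rt`, `z_er`, `z_ies` and the per-seed matrix.
#' @export
recover_behavioral_contrasts <- function(profile = paper_effects(), seeds = 1:60) {
  per_seed <- t(vapply(seeds, function(s) {
    st <- generate_study(profile, s, conditions = c("SIT", "MIC"))
    beh <- merge(zscore_measures(summarize_trials(st$trials)), st$covariates,
                 by = "subject")
    vapply(c("z_rt", "z_er", "z_ies"), function(m) {
      fit <- fit_lmm(lmm_spec(m, include_block = TRUE), beh)
      ct <- suppressMessages(emmeans_contrasts(fit))
      ct$estimate[grepl("MIC-SIT", ct$contrast)]
    }, numeric(1L))
  }, numeric(3L)))
  list(z_rt = mean(per_seed[, "z_rt"]), z_er = mean(per_seed[, "z_er"]),
       z_ies = mean(per_seed[, "z_ies"]), per_seed = per_seed)
}

#' Retinal caliber interaction recovery experiment
#'
#' Generates vessel widths in the two-condition reduced design, computes
#' CRAE/CRVE via the Knudtson reduction, fits the condition x timepoint
#' mixed model (treatment coding, control/pre reference), and averages the
#' interaction coefficient over seeds.
#'
#' @param profile An [effect_profile()].
#' @param seeds Integer vector of generator seeds.
#' @return List with mean `crae`, `crve` and the per-seed matrix.
#' @export
recover_retinal_interactions <- function(profile = paper_effects(), seeds = 1:20) {
  per_seed <- t(vapply(seeds, function(s) {
    idx <- retinal_indices_table(generate_vessel_widths(profile, s))
    vapply(c("crae", "crve"), function(m) {
      fit <- fit_lmm(lmm_spec(m, covariates = character(0)), idx)
      fit$coefficients$beta[fit$coefficients$term == "conditionEX:timepointpost"]
    }, numeric(1L))
  }, numeric(2L)))
  list(crae = mean(per_seed[, "crae"]), crve = mean(per_seed[, "crve"]),
       per_seed = per_seed)
}

#' Causal-density interaction recovery experiment
#'
#' Generates per-cell causal-density observations for the requested state,
#' fits the condition x timepoint mixed model, and averages the interaction
#' coefficient over seeds.
#'
#' @param profile An [effect_profile()].
#' @param state `"resting"` or `"task"`.
#' @param seeds Integer vector of generator seeds.
#' @return List with the mean `interaction` and per-seed values.
#' @export
recover_cd_interaction <- function(profile = paper_effects(),
                                   state = c("resting", "task"), seeds = 1:20) {
  state <- match.arg(state)
  per_seed <- vapply(seeds, function(s) {
    d <- generate_cd_observations(profile, state, s)
    fit <- fit_lmm(lmm_spec("causal_density", covariates = character(0)), d)
    fit$coefficients$beta[fit$coefficients$term == "conditionEX:timepointpost"]
  }, numeric(1L))
  list(interaction = mean(per_seed), per_seed = per_seed)
}
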