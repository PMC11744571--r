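#' Run the synthetic study analysis pipeline end to end
#'
#' Orchestrates the stages in dependency order on a generated study dataset:
#' behavioral scoring and z-normalization, retinal indices, the linear mixed
#' models with DiD contrasts for every outcome, and the mediation stage on
#' per-subject change scores. Writes tidy CSVs plus a manifest when
#' `out_dir` is given; reruns with an identical config reproduce identical
#' outputs.
#'
#' @param config List: `profile` (an [effect_profile()]), `seed`,
#'   `conditions`, `n_boot` (mediation bootstrap), optional `out_dir`.
#' @return List with `study`, `behavior` (z-scored summaries), `retina`,
#'   `lmm` (per-outcome fits and contrasts), `mediation`, `manifest`.
#' @export
run_study_pipeline <- function(config) {
  stopifnot(is.list(config))
  profile <- config$profile %||% paper_effects()
  seed <- config$seed %||% 1L
  conditions <- config$conditions %||% c("SIT", "MIC", "VIC")
  n_boot <- config$n_boot %||% 10000L
  validate_profile(profile)

  study <- generate_study(profile, seed, conditions)
  behavior <- zscore_measures(summarize_trials(study$trials))
  retina <- retinal_indices_table(study$vessel_widths)

  with_covariates <- function(d) merge(d, study$covariates, by = "subject")
  lmm_results <- list()
  beh <- with_covariates(behavior)
  for (meas in c("z_rt", "z_er", "z_ies")) {
    fit <- fit_lmm(lmm_spec(meas, include_block = TRUE,
                            ref_condition = conditions[1L],
                            ref_block = "baseline"), beh)
    lmm_results[[meas]] <- list(fit = fit, contrasts = emmeans_contrasts(fit))
  }
  ret <- with_covariates(retina)
  for (meas in c("crae", "crve", "avr")) {
    fit <- fit_lmm(lmm_spec(meas, ref_condition = conditions[1L]), ret)
    lmm_results[[meas]] <- list(fit = fit, contrasts = emmeans_contrasts(fit))
  }
  for (state in c("resting", "task")) {
    d <- with_covariates(study[[paste0("cd_", state)]])
    fit <- fit_lmm(lmm_spec("causal_density", ref_condition = conditions[1L]), d)
    lmm_results[[paste0("cd_", state)]] <- list(fit = fit,
                                                contrasts = emmeans_contrasts(fit))
  }

  med_data <- generate_mediation_dataset(profile$mediation_paths,
                                         n = profile$n_subjects,
                                         noise_sd = profile$noise_sds[["mediation"]],
                                         covariates = TRUE, seed = seed,
                                         profile = profile)
  mediation <- fit_mediation(med_data, covariates = TRUE, n_boot = n_boot,
                             seed = seed)

  manifest <- data.frame(
    stage = c("study", "behavior", "retina", "lmm", "mediation"),
    rows = c(nrow(study$trials), nrow(behavior), nrow(retina),
             length(lmm_results), nrow(mediation$paths)),
    seed = seed, n_subjects = profile$n_subjects,
    stringsAsFactors = FALSE
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(behavior, file.path(config$out_dir, "behavior_summaries.csv"),
              row.names = FALSE)
    write.csv(retina, file.path(config$out_dir, "retinal_indices.csv"),
              row.names = FALSE)
    contr <- do.call(rbind, lapply(names(lmm_results), function(nm) {
      cbind(outcome = nm, lmm_results[[nm]]$contrasts)
    }))
    write.csv(contr, file.path(config$out_dir, "lmm_contrasts.csv"),
              row.names = FALSE)
    write.csv(mediation$paths, file.path(config$out_dir, "mediation_paths.csv"),
              row.names = FALSE)
    write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(study = study, behavior = behavior, retina = retina, lmm = lmm_results,
       mediation = mediation, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
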