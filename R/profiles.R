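#' Construct a study effect profile
#'
#' An effect profile bundles everything the synthetic-data generators need to
#' emulate the crossover study: the injected post-pre
#' difference-in-differences per outcome and condition contrast, the
#' mediation path coefficients, noise standard deviations, the sample size
#' and the covariate distributions. Behavioral effects are expressed in
#' z-score units of the pre-intervention normalization pool; the generator
#' translates them to raw-scale shifts analytically (see
#' [calibrate_behavioral_generator()]).
#'
#' @param behavioral_dids Named list per measure (`rt`, `er`) of named
#'   vectors of z-unit DiDs per exercise condition. The IES DiD is implied by
#'   the RT and ER effects because IES is computed from them; the profile
#'   stores the intended value in `ies` for reference and calibration.
#' @param retinal_dids Named vector (`crae`, `crve`), micrometres, for the
#'   exercise-vs-control interaction in the two-condition reduced design.
#' @param cd_dids Named vector (`resting`, `task`), causal-density units.
#' @param cd_baseline,cd_noise_sds Baselines and residual SDs for the
#'   causal-density observation generator.
#' @param mediation_paths Named vector `a`, `b`, `c_prime`; the total effect
#'   `c = c_prime + a*b` holds by construction.
#' @param noise_sds Named vector of generator noise SDs (see
#'   [paper_effects()] for the members).
#' @param behavior Block-level behavioral parameters: baseline mean RTs per
#'   block (ms), base error probability, trials per block.
#' @param n_subjects Number of participants (>= 2).
#' @param covariates Covariate distribution parameters.
#' @return List of class `effect_profile`.
#' @export
effect_profile <- function(behavioral_dids, retinal_dids, cd_dids,
                           cd_baseline, cd_noise_sds, mediation_paths,
                           noise_sds, behavior, n_subjects, covariates) {
  p <- structure(list(
    behavioral_dids = behavioral_dids, retinal_dids = retinal_dids,
    cd_dids = cd_dids, cd_baseline = cd_baseline, cd_noise_sds = cd_noise_sds,
    mediation_paths = mediation_paths, noise_sds = noise_sds,
    behavior = behavior, n_subjects = as.integer(n_subjects),
    covariates = covariates
  ), class = "effect_profile")
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  if (!is.numeric(p$noise_sds) || any(p$noise_sds <= 0)) {
    stop_config("invalid profile field 'noise_sds': all noise SDs must be > 0")
  }
  if (p$n_subjects < 2L) {
    stop_config("invalid profile field 'n_subjects': must be >= 2")
  }
  mp <- p$mediation_paths
  if (!all(c("a", "b", "c_prime") %in% names(mp))) {
    stop_config("invalid profile field 'mediation_paths': needs a, b, c_prime")
  }
  if (any(p$cd_noise_sds <= 0)) {
    stop_config("invalid profile field 'cd_noise_sds': must be > 0")
  }
  b <- p$behavior
  if (b$er_base <= 0 || b$er_base >= 1) {
    stop_config("invalid profile field 'behavior$er_base': must be in (0,1)")
  }
  if (b$n_trials < 1L) {
    stop_config("invalid profile field 'behavior$n_trials': must be >= 1")
  }
  invisible(TRUE)
}

#' Total mediation effect implied by a profile
#'
#' @param profile An [effect_profile()].
#' @return `c = c_prime + a * b`.
#' @export
mediation_total_effect <- function(profile) {
  mp <- profile$mediation_paths
  unname(mp["c_prime"] + mp["a"] * mp["b"])
}

#' The packaged study effect profile
#'
#' Encodes the study conditions used throughout the recovery experiments:
#' 71 participants; behavioral z-unit DiDs of -0.13 (RT), -0.36 (ER) and
#' -0.20 (IES) for moderate exercise vs control, with the vigorous condition
#' adding -0.09/-0.17/-0.13; retinal caliber interactions of 4.46 um (CRAE)
#' and 6.34 um (CRVE); causal-density interactions of 0.37 (resting, residual
#' SD 0.1) and 0.06 (task, residual SD 0.02); and mediation paths a = 1.0,
#' b = -0.82, c' = -0.51 (total effect -1.33). Covariates follow the cohort:
#' ~51% female, age 20.9 +/- 1.9 years, BMI 23.0 +/- 4.3 (male) /
#' 20.4 +/- 3.1 (female).
#'
#' @return An [effect_profile()].
#' @export
paper_effects <- function() {
  effect_profile(
    behavioral_dids = list(
      rt  = c(MIC = -0.13, VIC = -0.22),
      er  = c(MIC = -0.36, VIC = -0.53),
      ies = c(MIC = -0.20, VIC = -0.33)
    ),
    retinal_dids = c(crae = 4.46, crve = 6.34),
    cd_dids = c(resting = 0.37, task = 0.06),
    cd_baseline = c(resting = 0.30, task = 0.05),
    cd_noise_sds = c(resting = 0.10, task = 0.02),
    mediation_paths = c(a = 1.0, b = -0.82, c_prime = -0.51),
    noise_sds = c(
      rt_trial = 80, rt_cell = 30,
      er_subject = 0.01, er_cell = 0.005,
      vessel = 1.0, retinal_cell = 3, retinal_subject = 5,
      cd_subject_resting = 0.05, cd_subject_task = 0.01,
      mediation = 0.1
    ),
    behavior = list(
      rt_block_means = c(baseline = 650, color_dual = 710, lexical_dual = 790),
      rt_time_main = -5,
      er_base = 0.05,
      n_trials = 36L
    ),
    n_subjects = 71L,
    covariates = list(
      sex_prop_female = 0.507,
      age = c(mean = 20.94, sd = 1.93),
      bmi_male = c(mean = 23.00, sd = 4.28),
      bmi_female = c(mean = 20.36, sd = 3.05)
    )
  )
}

#' Calibrate the raw-scale behavioral generator to the profile's z-effects
#'
#' The scoring pipeline computes IES from RT and ER, so the three z-unit
#' DiDs cannot be injected independently: once the RT and ER shifts and the
#' pool SDs are set, the IES z-effect is implied. This calibration makes the
#' triple mutually consistent. Writing `r` for the share ratio
#' `R * sd_ER / ((1-p) * sd_RT)` of the ER and RT contributions to the IES
#' pool SD (delta method, `R` = mean RT, `p` = base error rate), the implied
#' IES effect is `(z_rt + z_er * r) / sqrt(1 + r^2)`; solving for `r` and
#' then for the RT pool SD pins the RT between-subject SD, given the ER pool
#' SD (whose floor is the binomial trial noise at `n_trials` per cell) and
#' the RT trial/cell noise components.
#'
#' @param profile An [effect_profile()].
#' @return List: pool SDs (`sigma_rt_pool`, `sigma_er_pool`), variance
#'   components (`sigma_rt_subject`), expected reciprocal correct-trial count
#'   (`e_inv_ncorrect`), and raw-scale DiDs per condition (`delta_rt_ms`,
#'   `delta_er`).
#' @export
calibrate_behavioral_generator <- function(profile) {
  b <- profile$behavior
  ns <- profile$noise_sds
  p0 <- b$er_base
  nt <- b$n_trials
  lat_er <- ns[["er_subject"]]^2 + ns[["er_cell"]]^2
  sigma_er2 <- lat_er + (p0 * (1 - p0) - lat_er) / nt
  if (sigma_er2 <= 0) stop_config("invalid profile: ER variance components")
  sigma_er <- sqrt(sigma_er2)

  # E[1/n_correct | n_correct >= 1], n_correct ~ Binomial(nt, 1 - p0)
  j <- seq_len(nt)
  pj <- stats::dbinom(j, nt, 1 - p0)
  e_inv <- sum(pj / j) / sum(pj)

  zr <- profile$behavioral_dids$rt[["MIC"]]
  ze <- profile$behavioral_dids$er[["MIC"]]
  zi <- profile$behavioral_dids$ies[["MIC"]]
  rbar <- mean(b$rt_block_means)
  if (zr == 0 && ze == 0 && zi == 0) {
    # null profile: no constraint from the IES triple; use a plain
    # between-subject RT spread typical of dual-task Stroop cells
    sigma_rt <- sqrt(120^2 + ns[["rt_cell"]]^2 + ns[["rt_trial"]]^2 * e_inv)
    r <- rbar * sigma_er / ((1 - p0) * sigma_rt)
  } else {
    # solve (zr + ze r) = zi sqrt(1 + r^2) for r > 0
    qa <- ze^2 - zi^2
    qb <- 2 * zr * ze
    qc <- zr^2 - zi^2
    if (qa == 0) {
      if (qb == 0) stop_config("behavioral effect triple (rt, er, ies) is not jointly attainable")
      r <- -qc / qb
    } else {
      disc <- qb^2 - 4 * qa * qc
      if (disc < 0) stop_config("behavioral effect triple (rt, er, ies) is not jointly attainable")
      roots <- (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa)
      r <- roots[roots > 0]
    }
    if (length(r) == 0L || all(r <= 0)) {
      stop_config("behavioral effect triple (rt, er, ies) is not jointly attainable")
    }
    r <- min(r[r > 0])
    sigma_rt <- rbar * sigma_er / ((1 - p0) * r)
  }
  var_subject <- sigma_rt^2 - ns[["rt_cell"]]^2 - ns[["rt_trial"]]^2 * e_inv
  if (var_subject <= 0) {
    stop_config("RT noise components exceed the calibrated pool variance")
  }
  list(
    sigma_rt_pool = sigma_rt,
    sigma_er_pool = sigma_er,
    sigma_rt_subject = sqrt(var_subject),
    e_inv_ncorrect = e_inv,
    share_ratio = r,
    delta_rt_ms = profile$behavioral_dids$rt * sigma_rt,
    delta_er = profile$behavioral_dids$er * sigma_er
  )
}
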