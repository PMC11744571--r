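# Truncated-normal sampler by inverse-CDF; exact, vectorized.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  stats::qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

#' Generate participant covariates
#'
#' Sex (Bernoulli at the cohort female proportion), age and sex-specific BMI
#' from the profile's covariate distributions.
#'
#' @param profile An [effect_profile()].
#' @param seed Integer seed.
#' @return Data frame: `subject`, `sex` (0 male / 1 female), `age`, `bmi`.
#' @export
generate_covariates <- function(profile, seed) {
  cv <- profile$covariates
  n <- profile$n_subjects
  set.seed(child_seed(seed, 0L, salt = 11L))
  sex <- rbinom(n, 1L, cv$sex_prop_female)
  age <- rnorm(n, cv$age[["mean"]], cv$age[["sd"]])
  bmi <- ifelse(sex == 1L,
                rnorm(n, cv$bmi_female[["mean"]], cv$bmi_female[["sd"]]),
                rnorm(n, cv$bmi_male[["mean"]], cv$bmi_male[["sd"]]))
  data.frame(subject = sprintf("S%03d", seq_len(n)), sex = sex,
             age = age, bmi = pmax(bmi, 15), stringsAsFactors = FALSE)
}

#' Generate dual-task Stroop trials for the crossover design
#'
#' One cell per subject x condition x timepoint x block, each with
#' `n_trials` trials in the 50/25/25 congruent/incongruent/neutral mix.
#' Trial RTs are truncated-normal in (200, 3000) ms around a cell mean built
#' from a subject intercept, block effect, a small practice (time) effect and
#' the exercise effects; correctness is Bernoulli per trial. The
#' exercise-condition x post-intervention shifts are the raw-scale deltas
#' produced by [calibrate_behavioral_generator()], so the z-scored
#' difference-in-differences recover the profile's values in expectation.
#' Per-subject random streams are derived by a counter scheme, so a subject's
#' data do not depend on how many subjects are generated.
#'
#' @param profile An [effect_profile()].
#' @param seed Integer seed.
#' @param conditions Condition labels; the first is the control, any of
#'   `"MIC"`/`"VIC"` receive their profile effects.
#' @return Data frame of trials: `subject`, `condition`, `timepoint`,
#'   `block`, `trial`, `congruency`, `rt_ms`, `correct`.
#' @export
generate_behavioral_trials <- function(profile, seed,
                                       conditions = c("SIT", "MIC", "VIC")) {
  cal <- calibrate_behavioral_generator(profile)
  b <- profile$behavior
  ns <- profile$noise_sds
  nt <- b$n_trials
  blocks <- names(b$rt_block_means)
  n_mix <- round(nt * c(congruent = 0.5, incongruent = 0.25, neutral = 0.25))
  congruency_base <- rep(names(n_mix), times = n_mix)
  out <- vector("list", profile$n_subjects)
  for (i in seq_len(profile$n_subjects)) {
    set.seed(child_seed(seed, i, salt = 23L))
    subj_rt <- rnorm(1L, 0, cal$sigma_rt_subject)
    subj_er <- rnorm(1L, 0, ns[["er_subject"]])
    cells <- expand.grid(condition = conditions, timepoint = c("pre", "post"),
                         block = blocks, stringsAsFactors = FALSE)
    cell_rows <- vector("list", nrow(cells))
    for (cix in seq_len(nrow(cells))) {
      cond <- cells$condition[cix]; tp <- cells$timepoint[cix]
      blk <- cells$block[cix]
      exercise <- cond %in% names(cal$delta_rt_ms) && tp == "post"
      mu <- b$rt_block_means[[blk]] + subj_rt +
        (tp == "post") * b$rt_time_main +
        (if (exercise) cal$delta_rt_ms[[cond]] else 0) +
        rnorm(1L, 0, ns[["rt_cell"]])
      p_err <- b$er_base + subj_er +
        (if (exercise) cal$delta_er[[cond]] else 0) +
        rnorm(1L, 0, ns[["er_cell"]])
      p_err <- min(max(p_err, 0.001), 0.95)
      rt <- rtruncnorm(nt, mu, ns[["rt_trial"]], 200, 3000)
      correct <- runif(nt) > p_err
      cell_rows[[cix]] <- data.frame(
        subject = sprintf("S%03d", i), condition = cond, timepoint = tp,
        block = blk, trial = seq_len(nt),
        congruency = sample(congruency_base),
        rt_ms = rt, correct = correct, stringsAsFactors = FALSE
      )
    }
    out[[i]] <- do.call(rbind, cell_rows)
  }
  do.call(rbind, out)
}

#' Generate retinal vessel-width measurements for the crossover design
#'
#' Six arteriole and six venule widths per subject x condition x timepoint.
#' Cell-level target calibers (CRAE around 150 um, CRVE around 200 um) carry
#' a subject intercept, a residual cell effect, and the profile's
#' exercise x post interaction; the base width sets are rescaled so the
#' Knudtson reduction of the noise-free widths equals the target caliber,
#' then independent per-vessel measurement noise is added.
#'
#' @param profile An [effect_profile()].
#' @param seed Integer seed.
#' @param conditions Condition labels; conditions other than the first
#'   (control) receive the exercise effect. Default is the two-condition
#'   reduced design.
#' @return Long data frame: `subject`, `condition`, `timepoint`,
#'   `vessel_type`, `vessel`, `width_um`.
#' @export
generate_vessel_widths <- function(profile, seed, conditions = c("SIT", "EX")) {
  ns <- profile$noise_sds
  kc <- branching_constants()
  base_a <- c(98, 94, 90, 86, 82, 78)
  base_v <- c(118, 113, 108, 104, 100, 96)
  crae_base <- iterative_reduce(base_a, kc$k_arteriole)
  crve_base <- iterative_reduce(base_v, kc$k_venule)
  out <- vector("list", profile$n_subjects)
  for (i in seq_len(profile$n_subjects)) {
    set.seed(child_seed(seed, i, salt = 37L))
    subj_a <- rnorm(1L, 0, ns[["retinal_subject"]])
    subj_v <- rnorm(1L, 0, ns[["retinal_subject"]])
    cells <- expand.grid(condition = conditions, timepoint = c("pre", "post"),
                         stringsAsFactors = FALSE)
    rows <- vector("list", nrow(cells))
    for (cix in seq_len(nrow(cells))) {
      cond <- cells$condition[cix]; tp <- cells$timepoint[cix]
      did <- (cond != conditions[1L] && tp == "post")
      mu_a <- 150 + subj_a + did * profile$retinal_dids[["crae"]] +
        rnorm(1L, 0, ns[["retinal_cell"]])
      mu_v <- 200 + subj_v + did * profile$retinal_dids[["crve"]] +
        rnorm(1L, 0, ns[["retinal_cell"]])
      wa <- base_a * (mu_a / crae_base) + rnorm(6L, 0, ns[["vessel"]])
      wv <- base_v * (mu_v / crve_base) + rnorm(6L, 0, ns[["vessel"]])
      rows[[cix]] <- data.frame(
        subject = sprintf("S%03d", i), condition = cond, timepoint = tp,
        vessel_type = rep(c("arteriole", "venule"), each = 6L),
        vessel = rep(1:6, 2L), width_um = c(wa, wv), stringsAsFactors = FALSE
      )
    }
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Generate per-cell causal-density observations
#'
#' Causal-density values per subject x condition x timepoint for a given
#' state (resting or task), as baseline + subject intercept +
#' exercise x post interaction + residual noise, with SDs from the profile.
#'
#' @param profile An [effect_profile()].
#' @param state `"resting"` or `"task"`.
#' @param seed Integer seed.
#' @param conditions Condition labels; first = control.
#' @return Data frame: `subject`, `condition`, `timepoint`, `causal_density`.
#' @export
generate_cd_observations <- function(profile, state = c("resting", "task"),
                                     seed, conditions = c("SIT", "EX")) {
  state <- match.arg(state)
  did <- profile$cd_dids[[state]]
  base <- profile$cd_baseline[[state]]
  sd_cell <- profile$cd_noise_sds[[state]]
  sd_subj <- profile$noise_sds[[paste0("cd_subject_", state)]]
  salt <- if (state == "resting") 53L else 59L
  out <- vector("list", profile$n_subjects)
  for (i in seq_len(profile$n_subjects)) {
    set.seed(child_seed(seed, i, salt = salt))
    subj <- rnorm(1L, 0, sd_subj)
    cells <- expand.grid(condition = conditions, timepoint = c("pre", "post"),
                         stringsAsFactors = FALSE)
    cells$causal_density <- base + subj +
      (cells$condition != conditions[1L] & cells$timepoint == "post") * did +
      rnorm(nrow(cells), 0, sd_cell)
    cells$subject <- sprintf("S%03d", i)
    out[[i]] <- cells[, c("subject", "condition", "timepoint", "causal_density")]
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic study dataset
#'
#' Bundles covariates, behavioral trials, vessel widths and causal-density
#' observations for the full crossover design. Identical (profile, seed)
#' inputs reproduce identical output. fNIRS recordings are generated
#' separately by [generate_fnirs_recording()] because of their size.
#'
#' @param profile An [effect_profile()].
#' @param seed Integer seed.
#' @param conditions Condition labels (first = control).
#' @return List of class `study_dataset` with `covariates`, `trials`,
#'   `vessel_widths`, `cd_resting`, `cd_task`, `profile`, `seed`.
#' @export
generate_study <- function(profile, seed, conditions = c("SIT", "MIC", "VIC")) {
  validate_profile(profile)
  structure(list(
    covariates = generate_covariates(profile, seed),
    trials = generate_behavioral_trials(profile, seed, conditions),
    vessel_widths = generate_vessel_widths(profile, seed, conditions),
    cd_resting = generate_cd_observations(profile, "resting", seed, conditions),
    cd_task = generate_cd_observations(profile, "task", seed, conditions),
    profile = profile, seed = seed, conditions = conditions
  ), class = "study_dataset")
}

#' Generate a synthetic mediation dataset
#'
#' Per-subject change scores following the linear mediation model
#' `M = a X + e1`, `Y = c' X + b M + e2` with X standard normal, plus small
#' sex/age/BMI effects when covariates are enabled. Least-squares path
#' estimates are consistent for (a, b, c') as n grows, and the total effect
#' converges to `c' + a b`.
#'
#' @param paths Named vector `a`, `b`, `c_prime`.
#' @param n Sample size (>= 10).
#' @param noise_sd Error SD for both equations (> 0).
#' @param covariates Include sex/age/BMI columns and small covariate effects.
#' @param seed Integer seed.
#' @param profile Profile supplying the covariate distributions.
#' @return Data frame: `subject`, `x`, `m`, `y` (+ `sex`, `age`, `bmi`).
#' @export
generate_mediation_dataset <- function(paths, n = 71L, noise_sd = 0.1,
                                       covariates = TRUE, seed = 1L,
                                       profile = paper_effects()) {
  if (n < 10L) stop_config("at least 10 subjects are required (n = %d)", n)
  check_positive(noise_sd, "noise_sd")
  if (!all(c("a", "b", "c_prime") %in% names(paths))) {
    stop_config("'paths' must name a, b, c_prime")
  }
  set.seed(child_seed(seed, 0L, salt = 71L))
  x <- rnorm(n)
  d <- data.frame(subject = sprintf("S%03d", seq_len(n)), x = x,
                  stringsAsFactors = FALSE)
  m_cov <- y_cov <- 0
  if (covariates) {
    cv <- profile$covariates
    sex <- rbinom(n, 1L, cv$sex_prop_female)
    age <- rnorm(n, cv$age[["mean"]], cv$age[["sd"]])
    bmi <- ifelse(sex == 1L,
                  rnorm(n, cv$bmi_female[["mean"]], cv$bmi_female[["sd"]]),
                  rnorm(n, cv$bmi_male[["mean"]], cv$bmi_male[["sd"]]))
    d$sex <- sex; d$age <- age; d$bmi <- bmi
    m_cov <- 0.05 * sex + 0.01 * (age - cv$age[["mean"]])
    y_cov <- -0.05 * sex + 0.01 * (bmi - 22)
  }
  d$m <- paths[["a"]] * x + m_cov + rnorm(n, 0, noise_sd)
  d$y <- paths[["c_prime"]] * x + paths[["b"]] * d$m + y_cov + rnorm(n, 0, noise_sd)
  d
}
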