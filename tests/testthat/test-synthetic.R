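test_that("study generation is deterministic and emits the full design grid", {
  prof <- small_profile(6L)
  s1 <- generate_study(prof, seed = 42)
  s2 <- generate_study(prof, seed = 42)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$vessel_widths, s2$vessel_widths)
  expect_identical(s1$cd_resting, s2$cd_resting)
  s3 <- generate_study(prof, seed = 43)
  expect_false(identical(s1$trials$rt_ms, s3$trials$rt_ms))
  # one cell per subject x condition x timepoint (x block for trials)
  cells <- unique(s1$trials[, c("subject", "condition", "timepoint")])
  expect_equal(nrow(cells), 6L * 3L * 2L)
  expect_equal(nrow(s1$trials), 6L * 3L * 2L * 3L * 36L)
  # congruency mix is 50/25/25 within every block
  mix <- table(s1$trials$congruency[s1$trials$subject == "S001" &
                                      s1$trials$condition == "SIT" &
                                      s1$trials$timepoint == "pre" &
                                      s1$trials$block == "baseline"])
  expect_equal(as.integer(mix[c("congruent", "incongruent", "neutral")]),
               c(18L, 9L, 9L))
  expect_true(all(s1$trials$rt_ms > 200 & s1$trials$rt_ms < 3000))
})

test_that("subject-level streams do not depend on how many subjects are generated", {
  p6 <- small_profile(6L); p3 <- small_profile(3L)
  t6 <- generate_behavioral_trials(p6, seed = 5, conditions = c("SIT", "MIC"))
  t3 <- generate_behavioral_trials(p3, seed = 5, conditions = c("SIT", "MIC"))
  expect_identical(t3, t6[t6$subject %in% sprintf("S%03d", 1:3), ])
})

test_that("a null profile produces no condition differences beyond Monte-Carlo error", {
  p <- small_profile(25L)
  p$behavioral_dids <- lapply(p$behavioral_dids, function(v) v * 0)
  p$retinal_dids[] <- 0
  p$cd_dids[] <- 0
  dids <- vapply(1:8, function(s) {
    st <- generate_study(p, s, conditions = c("SIT", "MIC"))
    sm <- summarize_trials(st$trials)
    cm <- tapply(sm$mean_rt_correct_ms, list(sm$condition, sm$timepoint), mean)
    (cm["MIC", "post"] - cm["MIC", "pre"]) - (cm["SIT", "post"] - cm["SIT", "pre"])
  }, numeric(1))
  expect_lt(abs(mean(dids)), 3 * sd(dids) / sqrt(8))
})

test_that("invalid profile fields raise configuration errors naming the field", {
  p <- paper_effects()
  p$noise_sds[["mediation"]] <- -1
  expect_error(validate_profile(p), "noise_sds")
  p2 <- paper_effects(); p2$n_subjects <- 1L
  expect_error(validate_profile(p2), "n_subjects")
  p3 <- paper_effects(); p3$behavior$er_base <- 1.2
  expect_error(validate_profile(p3), "er_base")
})

test_that("injected behavioral and retinal effects are recovered in expectation", {
  # Monte-Carlo average of the raw difference-in-differences against the
  # calibrated injection, over independent seeds.
  p <- paper_effects()
  cal <- calibrate_behavioral_generator(p)
  p_small <- p; p_small$n_subjects <- 40L
  dids <- vapply(1:12, function(s) {
    tr <- generate_behavioral_trials(p_small, s, conditions = c("SIT", "MIC"))
    sm <- summarize_trials(tr)
    cm <- tapply(sm$mean_rt_correct_ms, list(sm$condition, sm$timepoint), mean)
    (cm["MIC", "post"] - cm["MIC", "pre"]) - (cm["SIT", "post"] - cm["SIT", "pre"])
  }, numeric(1))
  se <- sd(dids) / sqrt(length(dids))
  expect_lt(abs(mean(dids) - cal$delta_rt_ms[["MIC"]]), 3 * se)

  crae_did <- vapply(1:12, function(s) {
    vw <- generate_vessel_widths(p_small, s)
    idx <- retinal_indices_table(vw)
    cm <- tapply(idx$crae, list(idx$condition, idx$timepoint), mean)
    (cm["EX", "post"] - cm["EX", "pre"]) - (cm["SIT", "post"] - cm["SIT", "pre"])
  }, numeric(1))
  expect_lt(abs(mean(crae_did) - 4.46), 3 * sd(crae_did) / sqrt(12))
})

test_that("fNIRS synthesis validates stationarity, sampling and duration preconditions", {
  expect_error(var_ground_truth(3L, 1L, diag(1.2, 3)), "non-stationary")
  truth <- two_node_truth(0.5)
  expect_error(
    generate_fnirs_recording(nine_node_truth(), duration_s = 30, seed = 1),
    "at least 60"
  )
  expect_error(
    generate_fnirs_recording(nine_node_truth(), fs = 1.5, duration_s = 120, seed = 1),
    "aliases"
  )
  expect_error(
    generate_fnirs_recording(truth, duration_s = 120, seed = 1),
    "montage defines 9"
  )
})

test_that("a five-minute resting recording has 3060 samples per channel", {
  rec <- generate_fnirs_recording(nine_node_truth(), duration_s = 300,
                                  fs = 10.2, seed = 8)
  expect_equal(nrow(rec$intensity[[1]]), 3060L)
  expect_equal(ncol(rec$intensity[[1]]), 49L)
  expect_length(rec$intensity, 2L)
})

test_that("all-zero drive produces constant intensities", {
  truth <- var_ground_truth(9L, 1L, diag(0.3, 9), innovation_sd = 1e-12)
  silent <- noise_profile(cardiac = c(freq = 1.1, amp = 0),
                          respiration = c(freq = 0.25, amp = 0),
                          mayer = c(freq = 0.1, amp = 0),
                          drift_slope = 0, white_sd = 0)
  rec <- generate_fnirs_recording(truth, noise = silent, duration_s = 60,
                                  seed = 2, channel_noise_um = 0)
  ranges <- apply(rec$intensity[[1]], 2L, function(v) diff(range(v)))
  expect_lt(max(ranges), 1e-8)
})

test_that("a planted unidirectional coupling yields asymmetric downstream GC", {
  gcs <- t(vapply(1:5, function(s) {
    truth <- two_node_truth(0.5, self = 0.2)
    x <- simulate_var(truth, 3060, seed = 300 + s)
    g <- pairwise_conditional_gc(x, order = 1L)
    c(xy = g$gc[1, 2], yx = g$gc[2, 1])
  }, numeric(2)))
  expect_gt(mean(gcs[, "xy"]), mean(gcs[, "yx"]) + 0.05)
})
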