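# Balanced crossover generator with a known condition x time interaction,
# used for oracle comparisons against OLS and for recovery checks.
make_crossover <- function(n_subj, did, sd_subj = 1, sd_eps = 0.5, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("S%02d", 1:n_subj),
                   condition = c("SIT", "EX"), timepoint = c("pre", "post"),
                   stringsAsFactors = FALSE)
  subj_eff <- setNames(rnorm(n_subj, 0, sd_subj), sprintf("S%02d", 1:n_subj))
  d$y <- 10 + subj_eff[d$subject] +
    (d$condition == "EX" & d$timepoint == "post") * did +
    rnorm(nrow(d), 0, sd_eps)
  d
}

test_that("zero between-subject variance drives the random intercept to the boundary", {
  d <- make_crossover(30, did = 0, sd_subj = 0, sd_eps = 1, seed = 2)
  fit <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
  expect_lt(fit$varcomp[["subject"]], 0.05)
})

test_that("fixed effects match OLS on balanced data and the DiD equals the interaction term", {
  d <- make_crossover(40, did = 1.7, sd_subj = 0, sd_eps = 0.3, seed = 3)
  fit <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
  ols <- lm(y ~ relevel(factor(condition), "SIT") * relevel(factor(timepoint), "pre"),
            data = d)
  expect_equal(sort(unname(fit$coefficients$beta)), sort(unname(coef(ols))),
               tolerance = 1e-6)
  ct <- emmeans_contrasts(fit)
  inter <- fit$coefficients$beta[fit$coefficients$term == "conditionEX:timepointpost"]
  expect_equal(ct$estimate[grepl("EX-SIT", ct$contrast)], inter, tolerance = 1e-8)
})

test_that("a known interaction is recovered within 3 SE across seeds", {
  ests <- t(vapply(1:10, function(s) {
    d <- make_crossover(40, did = 0.8, sd_subj = 1, sd_eps = 0.5, seed = 100 + s)
    fit <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
    row <- fit$coefficients[fit$coefficients$term == "conditionEX:timepointpost", ]
    c(row$beta, row$se)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1]) - 0.8), 3 * mean(ests[, 2]) / sqrt(10))
})

test_that("null-effect data produce near-zero contrasts and calibrated tests", {
  ests <- vapply(1:15, function(s) {
    d <- make_crossover(30, did = 0, sd_subj = 1, sd_eps = 0.5, seed = 200 + s)
    fit <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
    ct <- emmeans_contrasts(fit)
    ct$estimate[grepl("EX-SIT", ct$contrast)]
  }, numeric(1))
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(15))
})

test_that("type-I error of the interaction test is near the nominal level", {
  pvals <- vapply(1:120, function(s) {
    d <- make_crossover(25, did = 0, sd_subj = 1, sd_eps = 0.5, seed = 3000 + s)
    fit <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
    fit$coefficients$p[fit$coefficients$term == "conditionEX:timepointpost"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / 120)
  expect_lt(abs(rate - 0.05), 0.05 + 2 * mc_se)  # generous band at 120 sims
  expect_gt(mean(pvals), 0.3)  # p-values roughly uniform, not degenerate
})

test_that("assumption checks pass on Gaussian residuals and trigger remediation on heavy tails", {
  d <- make_crossover(40, did = 0.5, sd_subj = 1, sd_eps = 0.5, seed = 11)
  fit <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
  chk <- check_assumptions(fit)
  expect_gt(chk$shapiro_p, 0.001)
  expect_true(chk$remediation %in% c("none", "transformed"))
  expect_true(is.list(chk$durbin_watson))

  set.seed(12)
  d$y <- d$y + c(stats::rt(nrow(d), df = 2)) * 2
  fit_t <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
  chk_t <- check_assumptions(fit_t, n_boot = 30L)
  expect_true(chk_t$remediation %in% c("transformed", "bootstrapped"))
  if (chk_t$remediation == "bootstrapped") {
    expect_true(all(chk_t$boot_ci$lower <= chk_t$boot_ci$upper))
  }
})

test_that("Shapiro-Wilk rejects heavy-tailed residuals at realistic sample size", {
  rejects <- vapply(1:20, function(s) {
    set.seed(400 + s)
    shapiro.test(stats::rt(426, df = 2))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rejects), 0.9)
})

test_that("identical data and spec reproduce the identical coefficient table", {
  d <- make_crossover(20, did = 0.4, seed = 13)
  f1 <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
  f2 <- fit_lmm(lmm_spec("y", covariates = character(0)), d)
  expect_identical(f1$coefficients, f2$coefficients)
})
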