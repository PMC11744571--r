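test_that("the total-effect identity c = c' + a*b holds at machine precision on any data", {
  set.seed(51)
  for (i in 1:5) {
    d <- data.frame(x = rnorm(40), m = rnorm(40), y = rnorm(40),
                    sex = rbinom(40, 1, 0.5), age = rnorm(40, 21, 2),
                    bmi = rnorm(40, 22, 3))
    fit <- fit_mediation(d, n_boot = 50L, seed = i)
    est <- setNames(fit$paths$estimate, fit$paths$path)
    expect_equal(est[["c"]], est[["c_prime"]] + est[["a"]] * est[["b"]],
                 tolerance = 1e-10)
    expect_equal(est[["indirect"]], est[["a"]] * est[["b"]], tolerance = 1e-12)
  }
  # the packaged path profile satisfies the same identity
  expect_equal(mediation_total_effect(paper_effects()), -1.33, tolerance = 1e-12)
})

test_that("paths are consistent at large n and near-null when the a-path is broken", {
  d <- generate_mediation_dataset(c(a = 1.0, b = -0.82, c_prime = -0.51),
                                  n = 10000L, noise_sd = 0.1, seed = 7)
  fit <- fit_mediation(d, n_boot = 50L, seed = 7)
  est <- setNames(fit$paths$estimate, fit$paths$path)
  expect_equal(est[["a"]], 1.0, tolerance = 0.01)
  expect_equal(est[["b"]], -0.82, tolerance = 0.01)
  expect_equal(est[["c_prime"]], -0.51, tolerance = 0.01)

  ind <- vapply(1:10, function(s) {
    d0 <- generate_mediation_dataset(c(a = 0, b = -0.8, c_prime = 0.3),
                                     n = 200L, noise_sd = 0.3, seed = s)
    f <- fit_mediation(d0, n_boot = 50L, seed = s)
    f$paths$estimate[f$paths$path == "indirect"]
  }, numeric(1))
  expect_lt(abs(mean(ind)), 3 * sd(ind) / sqrt(10) + 0.01)
})

test_that("bias-corrected bootstrap CI brackets the estimate and flags a broken mediation", {
  d <- generate_mediation_dataset(c(a = 1.0, b = -0.82, c_prime = -0.51),
                                  n = 71L, noise_sd = 0.1, seed = 3)
  fit <- fit_mediation(d, n_boot = 1000L, seed = 3)
  expect_true(all(fit$paths$ci_lower <= fit$paths$estimate + 1e-12))
  expect_true(all(fit$paths$ci_upper >= fit$paths$estimate - 1e-12))
  expect_true(fit$significant)

  covered <- vapply(1:20, function(s) {
    d0 <- generate_mediation_dataset(c(a = 0.8, b = 0, c_prime = 0.2),
                                     n = 71L, noise_sd = 0.3, seed = 100 + s)
    f <- fit_mediation(d0, n_boot = 300L, seed = s)
    row <- f$paths[f$paths$path == "indirect", ]
    row$ci_lower <= 0 && row$ci_upper >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.8)  # ~95% nominal, 20 replicates
})

test_that("bootstrap CI coverage for the indirect effect is near nominal at n = 71", {
  paths <- c(a = 0.6, b = -0.5, c_prime = 0.2)
  truth <- paths[["a"]] * paths[["b"]]
  covered <- vapply(1:60, function(s) {
    d <- generate_mediation_dataset(paths, n = 71L, noise_sd = 0.4,
                                    covariates = FALSE, seed = 500 + s)
    f <- fit_mediation(d, covariates = FALSE, n_boot = 400L, seed = s)
    row <- f$paths[f$paths$path == "indirect", ]
    row$ci_lower <= truth && row$ci_upper >= truth
  }, logical(1))
  mc_band <- 3 * sqrt(0.95 * 0.05 / 60)
  expect_gt(mean(covered), 0.95 - mc_band - 0.03)
})

test_that("mediation is deterministic given data and seed, and validates inputs", {
  d <- generate_mediation_dataset(c(a = 1, b = -0.8, c_prime = -0.5),
                                  n = 40L, noise_sd = 0.2, seed = 9)
  f1 <- fit_mediation(d, n_boot = 200L, seed = 11)
  f2 <- fit_mediation(d, n_boot = 200L, seed = 11)
  expect_identical(f1$paths, f2$paths)
  expect_error(generate_mediation_dataset(c(a = 1, b = 1, c_prime = 0), n = 5L,
                                          noise_sd = 0.1), "at least 10")
  expect_error(fit_mediation(d[1:6, ], n_boot = 10L), "at least 10")
  d_coll <- d; d_coll$m <- d_coll$x
  expect_error(fit_mediation(d_coll, n_boot = 10L), "collinearity")
})

test_that("correlation screening is calibrated under the null and detects planted signal", {
  set.seed(71)
  null_frac <- replicate(30, {
    d <- data.frame(matrix(rnorm(71 * 5), 71, 5))
    names(d) <- paste0("v", 1:5)
    out <- screen_correlations(d, covariates = character(0))
    mean(out$p < 0.05)
  })
  expect_lt(mean(null_frac), 0.05 + 2 * sqrt(0.05 * 0.95 / (30 * 10)))

  hits <- vapply(1:25, function(s) {
    set.seed(900 + s)
    x <- rnorm(71); y <- 0.8 * x + rnorm(71, 0, sqrt(1 - 0.64))
    d <- data.frame(x = x, y = y, z = rnorm(71))
    out <- screen_correlations(d, covariates = character(0))
    out$flagged[out$var1 == "x" & out$var2 == "y"]
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  # partialling out a confounder that fully explains the association
  set.seed(73)
  conf <- rnorm(200)
  d <- data.frame(p = conf + rnorm(200, 0, 0.1), q = -conf + rnorm(200, 0, 0.1),
                  noise = rnorm(200), cz = conf)
  out <- screen_correlations(d, covariates = "cz")
  expect_lt(abs(out$r[out$var1 == "p" & out$var2 == "q"]), 0.15)
})
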