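sim_var2 <- function(n, seed) {
  # VAR(2) with known coefficients for order-recovery checks
  A1 <- matrix(c(0.5, 0.1, 0, 0.4), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.3, 0, 0.2, -0.2), 2, 2, byrow = TRUE)
  truth <- var_ground_truth(2L, 2L, list(A1, A2))
  simulate_var(truth, n, seed)
}

test_that("BIC selects the generating order and recovers coefficients", {
  hits <- vapply(1:10, function(s) {
    fit_var(sim_var2(3000, s), max_order = 6)$order == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  m <- fit_var(sim_var2(3000, 99), max_order = 6, order = 2L)
  expect_lt(abs(m$A[[1]][1, 1] - 0.5), 0.1)
  expect_lt(abs(m$A[[2]][2, 1] - 0.2), 0.1)
  expect_true(m$stable)
  expect_lt(m$spectral_radius, 1)
})

test_that("white noise yields near-zero VAR coefficients", {
  set.seed(61)
  x <- matrix(rnorm(3000 * 3), ncol = 3)
  m <- fit_var(x, max_order = 5, order = 1L)
  expect_lt(max(abs(m$A[[1]])), 0.1)
})

test_that("unstable ground truths are rejected at construction and at fit", {
  expect_error(var_ground_truth(2L, 1L, diag(1.05, 2)), "non-stationary")
  set.seed(62)
  explosive <- matrix(0, 300, 2)
  for (t in 2:300) explosive[t, ] <- 1.04 * explosive[t - 1, ] + rnorm(2)
  expect_error(fit_var(explosive, max_order = 2, order = 1L), "unstable")
})

test_that("pairwise-conditional GC converges to the closed-form population value", {
  # x_t = eps, y_t = 0.5 x_{t-1} + eta  ->  GC(x->y) = ln(1.25), GC(y->x) = 0
  target <- log(1.25)
  for (n in c(500, 3000, 10000)) {
    gcs <- t(vapply(1:8, function(s) {
      x <- simulate_var(two_node_truth(0.5), n, seed = s * 1000 + n)
      g <- pairwise_conditional_gc(x, order = 1L)
      c(xy = g$gc[1, 2], yx = g$gc[2, 1])
    }, numeric(2)))
    expect_equal(mean(gcs[, "xy"]), target, tolerance = max(0.02, 3 / sqrt(n)))
    expect_lt(mean(gcs[, "yx"]), 0.02)
  }
})

test_that("GC matrices are equivariant under relabeling of the series", {
  set.seed(63)
  x <- simulate_var(nine_node_truth(), 800, seed = 5)
  colnames(x) <- paste0("roi", 1:9)
  g1 <- pairwise_conditional_gc(x, order = 1L)
  perm <- c(3, 1, 2, 9, 5, 4, 8, 7, 6)
  g2 <- pairwise_conditional_gc(x[, perm], order = 1L)
  expect_equal(g2$gc[colnames(x), colnames(x)], g1$gc, tolerance = 1e-10)
})

test_that("planted edges dominate non-edges in a nine-node network", {
  truth <- nine_node_truth(0.35)
  planted <- attr(truth, "planted")
  planted_gc <- numeric(0); null_gc <- numeric(0)
  for (s in 1:6) {
    x <- simulate_var(truth, 3060, seed = 70 + s)
    g <- pairwise_conditional_gc(x, order = 1L)
    is_planted <- matrix(FALSE, 9, 9)
    is_planted[planted] <- TRUE
    off <- !diag(9)
    planted_gc <- c(planted_gc, g$gc[is_planted])
    null_gc <- c(null_gc, g$gc[off & !is_planted])
  }
  expect_gt(median(planted_gc), quantile(null_gc, 0.95))
})

test_that("causal density counts FDR-significant edges out of the 72 ordered pairs", {
  x <- simulate_var(nine_node_truth(0.4), 3060, seed = 81)
  g <- pairwise_conditional_gc(x, order = 1L)
  cd <- causal_density(g)
  expect_equal(cd$unweighted, sum(g$significant, na.rm = TRUE) / 72)
  expect_equal(cd$weighted, mean(g$gc[!diag(9)]))
  expect_gte(cd$unweighted, 4 / 72)  # planted edges detected
  # degenerate extremes
  g_none <- g; g_none$significant[] <- FALSE
  expect_equal(causal_density(g_none)$unweighted, 0)
  g_all <- g; g_all$significant[!diag(9)] <- TRUE
  expect_equal(causal_density(g_all)$unweighted, 1)
})

test_that("FDR controls the false-edge rate on independent series", {
  dens <- vapply(1:60, function(s) {
    set.seed(9000 + s)
    x <- matrix(rnorm(400 * 5), ncol = 5)
    causal_density(pairwise_conditional_gc(x, order = 1L))$unweighted
  }, numeric(1))
  expect_lt(mean(dens), 0.05)
})

test_that("residual whiteness p-values are recorded and sane on well-specified data", {
  x <- simulate_var(two_node_truth(0.5), 2000, seed = 91)
  m <- fit_var(x, order = 1L)
  expect_length(m$whiteness_p, 2L)
  expect_true(all(m$whiteness_p >= 0 & m$whiteness_p <= 1))
  expect_gt(min(m$whiteness_p), 0.001)
})
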