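test_that("optical density conversion is zero for constant intensity and exact for spikes", {
  const <- matrix(1, 100, 3)
  expect_equal(intensity_to_od(const), matrix(0, 100, 3))
  # one sample at exactly a tenth of the column mean -> OD 1 there
  v <- c(rep(10, 99), 990 / 999)  # solves w = mean(c(rep(10,99), w)) / 10
  od2 <- intensity_to_od(cbind(v))
  expect_equal(od2[100], 1, tolerance = 1e-12)
  expect_error(intensity_to_od(matrix(c(1, -1, 1, 1), 2)), "non-positive intensity")
})

test_that("channel CV quality check excludes at and above the 15% boundary", {
  n <- 200
  mk <- function(cv) {
    v <- 100 + c(-1, 1) * cv * 100 * sqrt((n - 1) / n)  # sd/mean = cv exactly
    rep(v, n / 2)
  }
  x <- cbind(flat = rep(100, n), ok = mk(0.10), edge = mk(0.15), bad = mk(0.20))
  qc <- channel_quality_check(x)
  expect_true(all(c("flat", "ok") %in% qc$retained))
  expect_true(all(c("edge", "bad") %in% qc$excluded))  # "equal to or higher"
})

test_that("MBLL inversion is exact on forward-constructed OD and linear", {
  params <- mbll_params()
  set.seed(9)
  hbo <- matrix(rnorm(300, 0, 1e-3), 100, 3)
  hbr <- matrix(rnorm(300, 0, 5e-4), 100, 3)
  od <- hemoglobin_to_od(hbo, hbr, params)
  rec <- od_to_hemoglobin(od, params)
  expect_equal(rec$hbo, hbo, tolerance = 1e-12)
  expect_equal(rec$hbr, hbr, tolerance = 1e-12)
  rec2 <- od_to_hemoglobin(lapply(od, function(m) 2 * m), params)
  expect_equal(rec2$hbo, 2 * hbo, tolerance = 1e-12)
  zero <- od_to_hemoglobin(list(matrix(0, 10, 2), matrix(0, 10, 2)), params)
  expect_true(all(zero$hbo == 0) && all(zero$hbr == 0))
  bad_e <- matrix(c(1, 1, 1, 1), 2)
  expect_error(mbll_params(extinction = bad_e), "ill-conditioned")
})

test_that("band-pass keeps the 0.01-0.08 Hz band and removes cardiac and DC components", {
  fs <- 10.2
  tt <- seq(0, 600, by = 1 / fs)
  amp <- function(v) (max(v) - min(v)) / 2
  mid <- seq(round(length(tt) * 0.25), round(length(tt) * 0.75))
  pass <- bandpass(sin(2 * pi * 0.04 * tt), fs = fs)
  expect_gt(amp(pass[mid]), 0.95)
  expect_lt(amp(pass[mid]), 1.05)
  cardiac <- bandpass(sin(2 * pi * 1.0 * tt), fs = fs)
  expect_lt(max(abs(cardiac[mid])), 0.1)
  dc <- bandpass(rep(3, length(tt)), fs = fs)
  expect_lt(max(abs(dc[mid])), 0.05)
  expect_error(bandpass(rnorm(30), fs = fs), "too short")
  expect_error(bandpass(rnorm(1000), fs = 0.1), "sampling rate too low")
})

test_that("PCA denoising removes an injected common mode and preserves orthogonality", {
  set.seed(31)
  n <- 500
  clean <- matrix(rnorm(n * 8, 0, 0.1), n, 8)
  global <- sin(2 * pi * 0.1 * seq_len(n) / 10)
  x <- clean + global %*% t(rep(1, 8))
  den <- pca_denoise(x, 1L)
  resid_power <- mean(rowMeans(den)^2)
  inj_power <- mean(global^2)
  expect_lt(resid_power / inj_power, 0.01)
  expect_equal(pca_denoise(x, 0L), x)
  # cleaned data orthogonal to removed spatial components
  xc <- sweep(x, 2, colMeans(x))
  v1 <- svd(xc)$v[, 1]
  dc <- sweep(den, 2, colMeans(den))
  expect_lt(max(abs(dc %*% v1)) / sqrt(sum(xc^2)), 1e-8)
  expect_error(pca_denoise(x, 8L), "n_components")
})

test_that("ROI averaging follows the packaged nine-ROI montage", {
  m <- default_montage()
  expect_equal(sort(unique(m$assignment$roi)), 1:9)
  sizes <- table(m$assignment$roi)
  expect_equal(unname(sizes[["1"]]), 3L)  # medial frontal: three channels
  expect_equal(nrow(m$assignment), 49L)
  n <- 50
  x <- matrix(rnorm(n * 49), n, 49, dimnames = list(NULL, m$assignment$channel))
  ra <- roi_average(x, m)
  mf <- m$assignment$channel[m$assignment$roi == 1]
  expect_equal(ra$series[, "roi1"], rowMeans(x[, mf]))
  # identical member channels: ROI equals any member
  x2 <- x; for (ch in mf) x2[, ch] <- x[, mf[1]]
  expect_equal(roi_average(x2, m)$series[, "roi1"], x[, mf[1]])
  # dropping all channels of an ROI warns and flags
  expect_warning(ra3 <- roi_average(x, m, retained = setdiff(colnames(x), mf)),
                 "roi1")
  expect_false("roi1" %in% colnames(ra3$series))
})

test_that("preprocessing recovers latent ROI HbO from a noise-free recording", {
  truth <- nine_node_truth()
  silent <- noise_profile(cardiac = c(freq = 1.1, amp = 0),
                          respiration = c(freq = 0.25, amp = 0),
                          mayer = c(freq = 0.1, amp = 0),
                          drift_slope = 0, white_sd = 0)
  rec <- generate_fnirs_recording(truth, noise = silent, duration_s = 120,
                                  seed = 4, channel_noise_um = 0)
  out <- preprocess_recording(rec$intensity, filter_band = NULL,
                              pca_components = 0L)
  latent_c <- sweep(rec$latent_hbo, 2, colMeans(rec$latent_hbo))
  rec_um <- out$hbo * 1e3  # mM -> uM
  rec_c <- sweep(rec_um, 2, colMeans(rec_um))
  expect_lt(max(abs(unname(rec_c) - unname(latent_c))), 1e-8)
  for (r in 1:9) expect_gt(cor(out$hbo[, r], rec$latent_hbo[, r]), 0.99)
})
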