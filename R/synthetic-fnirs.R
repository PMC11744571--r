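#' Define a ground-truth VAR network for fNIRS synthesis
#'
#' @param n_nodes Number of latent (ROI-level) nodes.
#' @param order Lag order p.
#' @param coefficients List of p (n_nodes x n_nodes) lag-coefficient
#'   matrices, or a single matrix for p = 1.
#' @param innovation_sd Innovation SD per node (recycled).
#' @return List of class `var_ground_truth` with `n_nodes`, `order`, `A`,
#'   `innovation_sd`, `edge_set` (nonzero off-diagonal couplings: `from`,
#'   `to`, `lag`, `weight`) and `spectral_radius`. Errors if the companion
#'   spectral radius is >= 1.
#' @export
var_ground_truth <- function(n_nodes, order = 1L, coefficients,
                             innovation_sd = 1) {
  if (is.matrix(coefficients)) coefficients <- list(coefficients)
  if (length(coefficients) != order) stop_config("need one coefficient matrix per lag")
  for (A in coefficients) {
    if (!all(dim(A) == c(n_nodes, n_nodes))) {
      stop_config("coefficient matrices must be %d x %d", n_nodes, n_nodes)
    }
  }
  radius <- companion_radius(coefficients)
  if (radius >= 1) {
    stop_config("ground-truth VAR is non-stationary (spectral radius %.3f)", radius)
  }
  edges <- do.call(rbind, lapply(seq_along(coefficients), function(l) {
    idx <- which(coefficients[[l]] != 0 & !diag(n_nodes), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    # A[j, i] couples lagged node i into node j: edge i -> j
    data.frame(from = idx[, 2L], to = idx[, 1L], lag = l,
               weight = coefficients[[l]][idx])
  }))
  structure(list(
    n_nodes = n_nodes, order = as.integer(order), A = coefficients,
    innovation_sd = rep_len(innovation_sd, n_nodes),
    edge_set = edges, spectral_radius = radius
  ), class = "var_ground_truth")
}

#' Physiological noise profile for fNIRS synthesis
#'
#' Cardiac, respiratory and Mayer-wave sinusoids (frequency in Hz, amplitude
#' in optical-density units), a linear drift (OD per second) and white
#' measurement noise (OD).
#'
#' @param cardiac,respiration,mayer Named vectors `c(freq, amp)`.
#' @param drift_slope OD drift per second.
#' @param white_sd White-noise SD (OD).
#' @return List of class `fnirs_noise_profile`.
#' @export
noise_profile <- function(cardiac = c(freq = 1.1, amp = 2e-3),
                          respiration = c(freq = 0.25, amp = 1e-3),
                          mayer = c(freq = 0.1, amp = 8e-4),
                          drift_slope = 2e-5, white_sd = 5e-4) {
  for (comp in list(cardiac, respiration, mayer)) {
    if (comp[["freq"]] <= 0) stop_config("oscillation frequencies must be > 0")
    if (comp[["amp"]] < 0) stop_config("oscillation amplitudes must be >= 0")
  }
  if (white_sd < 0) stop_config("white_sd must be >= 0")
  structure(list(cardiac = cardiac, respiration = respiration, mayer = mayer,
                 drift_slope = drift_slope, white_sd = white_sd),
            class = "fnirs_noise_profile")
}

#' Simulate a stationary VAR time series
#'
#' @param truth A [var_ground_truth()].
#' @param n Samples to return (after a burn-in of 200).
#' @param seed Integer seed.
#' @return n x n_nodes matrix.
#' @export
simulate_var <- function(truth, n, seed) {
  set.seed(child_seed(seed, 0L, salt = 83L))
  k <- truth$n_nodes; p <- truth$order
  burn <- 200L
  total <- n + burn + p
  x <- matrix(0, total, k)
  innov <- matrix(rnorm(total * k), total, k) %*% diag(truth$innovation_sd, k)
  for (t in (p + 1L):total) {
    acc <- innov[t, ]
    for (l in seq_len(p)) acc <- acc + drop(truth$A[[l]] %*% x[t - l, ])
    x[t, ] <- acc
  }
  x[(burn + p + 1L):total, , drop = FALSE]
}

#' Forward modified Beer-Lambert projection
#'
#' Maps HbO/HbR concentration changes (mM) to optical-density changes at the
#' two wavelengths: `dOD(lambda) = (e_hbo dHbO + e_hbr dHbR) * d * DPF`.
#' Exact inverse of [od_to_hemoglobin()].
#'
#' @param hbo,hbr Matrices (time x channels), mM.
#' @param params An [mbll_params()].
#' @return List of two OD matrices ordered as the extinction rows.
#' @export
hemoglobin_to_od <- function(hbo, hbr, params = mbll_params()) {
  e <- params$extinction
  scale <- params$distance_cm * params$dpf
  list(
    e[1L, 1L] * hbo * scale + e[1L, 2L] * hbr * scale,
    e[2L, 1L] * hbo * scale + e[2L, 2L] * hbr * scale
  )
}

#' Generate a two-wavelength fNIRS intensity recording
#'
#' Forward model: a latent stable VAR network at ROI level provides the
#' spontaneous neural signal; task blocks (if any) add a canonical-HRF
#' response to the active ROIs; ROI hemoglobin is copied to member channels
#' with independent channel noise; concentrations are projected to 760/850 nm
#' optical densities by the forward Beer-Lambert relation; physiological
#' oscillations, drift and white noise are added in OD; and intensities are
#' `I0 * 10^(-OD)`. The noise-free output inverts exactly through the
#' preprocessing MBLL (up to per-channel mean centering).
#'
#' @param truth A [var_ground_truth()] with one node per ROI in the montage.
#' @param task_design Optional block schedule (`onset_s`, `duration_s`,
#'   `type`) plus an `active_rois` attribute or list element; `NULL` for a
#'   resting recording.
#' @param noise A [noise_profile()]; use zero amplitudes for a clean
#'   recording.
#' @param duration_s Recording length, seconds (>= 60).
#' @param fs Sampling rate, Hz (must exceed twice the cardiac frequency).
#' @param seed Integer seed.
#' @param montage Channel montage.
#' @param params MBLL parameters (shared with the inverse).
#' @param var_scale_um Scale of spontaneous HbO fluctuations in micromolar
#'   per unit VAR amplitude.
#' @param task_amplitude_um Peak task HbO response, micromolar.
#' @param channel_noise_um Channel-level HbO noise SD, micromolar.
#' @param active_rois ROI indices receiving the task response.
#' @return List of class `fnirs_recording`: `intensity` (list of two
#'   time x channel matrices), `latent_hbo` (time x ROI, micromolar), `fs`,
#'   `montage`, `truth`, `task_design`.
#' @export
generate_fnirs_recording <- function(truth, task_design = NULL,
                                     noise = noise_profile(),
                                     duration_s = 300, fs = 10.2, seed = 1L,
                                     montage = default_montage(),
                                     params = mbll_params(),
                                     var_scale_um = 0.4,
                                     task_amplitude_um = 1.0,
                                     channel_noise_um = 0.05,
                                     active_rois = integer(0)) {
  if (duration_s < 60) stop_config("duration must be at least 60 s")
  if (fs <= 2 * noise$cardiac[["freq"]]) {
    stop_config("sampling rate %.3g Hz aliases the cardiac band (%.3g Hz)",
                fs, noise$cardiac[["freq"]])
  }
  n <- round(duration_s * fs)
  rois <- sort(unique(montage$assignment$roi))
  if (truth$n_nodes != length(rois)) {
    stop_config("ground truth has %d nodes but montage defines %d ROIs",
                truth$n_nodes, length(rois))
  }
  latent <- simulate_var(truth, n, seed) * var_scale_um
  if (!is.null(task_design) && nrow(task_design)) {
    des <- build_design(task_design, n, fs = fs, drift_order = 0L)
    task_sig <- rowSums(des$X[, des$task_columns, drop = FALSE]) * task_amplitude_um
    for (r in active_rois) latent[, r] <- latent[, r] + task_sig
  }
  colnames(latent) <- paste0("roi", rois)

  assignment <- montage$assignment
  channels <- assignment$channel
  set.seed(child_seed(seed, 1L, salt = 97L))
  hbo_um <- latent[, match(assignment$roi, rois), drop = FALSE] +
    matrix(rnorm(n * length(channels), 0, channel_noise_um), n, length(channels))
  colnames(hbo_um) <- channels
  hbr_um <- -0.3 * hbo_um  # typical anticorrelated HbR response
  od <- hemoglobin_to_od(hbo_um * 1e-3, hbr_um * 1e-3, params)

  tt <- seq_len(n) / fs
  osc <- function(comp, phase) comp[["amp"]] * sin(2 * pi * comp[["freq"]] * tt + phase)
  intensity <- lapply(od, function(od_w) {
    noise_od <- matrix(0, n, length(channels))
    for (ci in seq_along(channels)) {
      phases <- runif(3L, 0, 2 * pi)
      noise_od[, ci] <- osc(noise$cardiac, phases[1L]) +
        osc(noise$respiration, phases[2L]) +
        osc(noise$mayer, phases[3L]) +
        noise$drift_slope * tt +
        rnorm(n, 0, noise$white_sd)
    }
    out <- 10^(-(od_w + noise_od))
    colnames(out) <- channels
    out
  })
  names(intensity) <- rownames(params$extinction)
  structure(list(intensity = intensity, latent_hbo = latent, fs = fs,
                 montage = montage, truth = truth, task_design = task_design),
            class = "fnirs_recording")
}
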