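#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a gamma response peaking near 6 s minus a
#' later gamma undershoot near 16 s with ratio 1/6, normalized to unit peak.
#'
#' @param t Time points in seconds (>= 0).
#' @param peak,undershoot Gamma shape parameters (seconds, rate 1).
#' @param ratio Undershoot amplitude relative to the response.
#' @return HRF values at `t`, max-normalized to 1.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- dgamma(t, shape = peak, rate = 1) - ratio * dgamma(t, shape = undershoot, rate = 1)
  grid <- seq(0, 40, by = 0.01)
  hmax <- max(dgamma(grid, shape = peak, rate = 1) -
                ratio * dgamma(grid, shape = undershoot, rate = 1))
  h / hmax
}

#' Build a GLM design matrix from a block schedule
#'
#' One regressor per block type: the block indicator convolved with the
#' peak-normalized canonical HRF. Zero-duration events yield the HRF shape
#' itself (unit-mass impulse); finite boxcars are convolved in continuous-time
#' units so a long block plateaus near the HRF integral. Drift is modeled by
#' per-segment polynomial columns (default order 3) plus an intercept.
#'
#' @param schedule Data frame with columns `onset_s`, `duration_s`, `type`.
#'   May be empty (intercept/drift-only design).
#' @param n_samples Number of time samples in the recording.
#' @param fs Sampling rate, Hz.
#' @param hrf_params List of [canonical_hrf()] parameters.
#' @param drift_order Polynomial drift order (0 = intercept only).
#' @return List of class `fnirs_design` with `X` (matrix), `task_columns`,
#'   `fs`, `hrf` (the sampled kernel).
#' @export
build_design <- function(schedule, n_samples, fs = 10.2,
                         hrf_params = list(), drift_order = 3L) {
  if (is.null(schedule)) schedule <- data.frame(onset_s = numeric(), duration_s = numeric(),
                                               type = character())
  if (nrow(schedule)) {
    if (any(schedule$onset_s < 0) ||
        any(schedule$onset_s + schedule$duration_s > n_samples / fs + 1e-9)) {
      stop_config("schedule extends beyond the recording span")
    }
    ord <- order(schedule$onset_s)
    s <- schedule[ord, ]
    same <- which(diff(s$onset_s) < head(s$duration_s, -1) &
                    head(s$type, -1) == tail(s$type, -1))
    if (length(same)) stop_config("overlapping blocks of identical type in schedule")
  }
  t_kernel <- seq(0, 32, by = 1 / fs)
  kernel <- do.call(canonical_hrf, c(list(t = t_kernel), hrf_params))
  types <- unique(as.character(schedule$type))
  task <- matrix(0, n_samples, length(types), dimnames = list(NULL, types))
  for (ty in types) {
    stim <- numeric(n_samples)
    rows <- schedule[schedule$type == ty, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      i0 <- floor(rows$onset_s[r] * fs) + 1L
      if (rows$duration_s[r] <= 0) {
        stim[i0] <- stim[i0] + fs  # unit-mass impulse
      } else {
        i1 <- min(n_samples, floor((rows$onset_s[r] + rows$duration_s[r]) * fs))
        stim[i0:i1] <- stim[i0:i1] + 1
      }
    }
    conv <- convolve(stim, rev(kernel), type = "open")[seq_len(n_samples)] / fs
    task[, ty] <- conv
  }
  tt <- seq_len(n_samples) / n_samples
  drift <- if (drift_order > 0L) {
    d <- sapply(seq_len(drift_order), function(k) tt^k)
    colnames(d) <- paste0("drift", seq_len(drift_order))
    d
  } else NULL
  X <- cbind(intercept = rep(1, n_samples), task, drift)
  if (qr(X)$rank < ncol(X)) stop_config("design matrix is rank deficient")
  structure(list(X = X, task_columns = types, fs = fs, hrf = kernel),
            class = "fnirs_design")
}

# Levinson-Durbin over all AR orders 0..max from the autocovariance; returns
# the innovation-variance path so BIC can pick the order in one pass.
levinson_path <- function(x, max_order) {
  n <- length(x)
  max_order <- min(max_order, n - 2L)
  acov <- stats::acf(x, lag.max = max_order, type = "covariance",
                     plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
  v <- numeric(max_order + 1L)
  v[1L] <- acov[1L]
  phis <- vector("list", max_order + 1L)
  phis[[1L]] <- numeric(0)
  phi <- numeric(0)
  for (p in seq_len(max_order)) {
    num <- acov[p + 1L] - if (p > 1L) sum(phi * acov[p:2L]) else 0
    k <- num / v[p]
    phi <- if (p > 1L) c(phi - k * rev(phi), k) else k
    v[p + 1L] <- v[p] * (1 - k^2)
    phis[[p + 1L]] <- phi
  }
  list(var_pred = v, coefs = phis)
}

select_ar_order <- function(x, max_order) {
  lp <- levinson_path(x, max_order)
  n <- length(x)
  orders <- seq_along(lp$var_pred) - 1L
  bic <- n * log(pmax(lp$var_pred, 1e-300)) + orders * log(n)
  p <- orders[which.min(bic)]
  list(order = p, coefs = lp$coefs[[p + 1L]])
}

prewhiten <- function(v, phi) {
  p <- length(phi)
  if (p == 0L) return(v)
  n <- length(v)
  out <- v[(p + 1L):n]
  for (j in seq_len(p)) out <- out - phi[j] * v[(p + 1L - j):(n - j)]
  out
}

#' Fit a channel GLM by autoregressive iteratively reweighted least squares
#'
#' Alternates (i) BIC-selected AR(p) modeling of the residuals, (ii)
#' pre-whitening of both response and design by the fitted AR filter, and
#' (iii) robust bisquare-weighted least squares on the whitened data, until
#' the coefficient change falls below `tol` or `max_iter` iterations. The AR
#' step corrects serially correlated errors; the robust step down-weights
#' motion-artifact outliers.
#'
#' @param y Response time series.
#' @param design A [build_design()] object or a plain design matrix.
#' @param max_ar_order Maximum AR order screened by BIC (default 41, about
#'   four seconds of lags at 10.2 Hz).
#' @param tukey Bisquare tuning constant (default 4.685).
#' @param max_iter,tol Convergence controls.
#' @return List with `beta`, `se`, `ar_order`, `ar_coefs`, `weights` (robust
#'   weights on the whitened samples, in \[0, 1\]), `iterations`, `converged`.
#' @export
fit_ar_irls <- function(y, design, max_ar_order = 41L, tukey = 4.685,
                        max_iter = 20L, tol = 1e-6) {
  X <- if (inherits(design, "fnirs_design")) design$X else as.matrix(design)
  if (length(y) != nrow(X)) stop_config("'y' and design length mismatch")
  if (length(y) <= ncol(X) + max_ar_order) {
    stop_config("series too short for the requested design and AR order")
  }
  if (qr(X)$rank < ncol(X)) stop_config("design matrix is rank deficient")
  beta <- qr.coef(qr(X), y)
  ar <- list(order = 0L, coefs = numeric(0))
  rfit <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    res <- y - drop(X %*% beta)
    ar <- select_ar_order(res, max_ar_order)
    yw <- prewhiten(y, ar$coefs)
    Xw <- apply(X, 2L, prewhiten, phi = ar$coefs)
    rfit <- suppressWarnings(
      MASS::rlm(Xw, yw, psi = MASS::psi.bisquare, c = tukey, maxit = 50)
    )
    beta_new <- coef(rfit)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  se <- sqrt(diag(vcov(rfit)))
  names(beta) <- colnames(X)
  list(beta = beta, se = se, ar_order = ar$order, ar_coefs = ar$coefs,
       weights = rfit$w, iterations = it, converged = converged)
}

#' Group-level activation means with FDR correction
#'
#' Averages channel betas within ROI per subject first (when a `channel`
#' column is present), then computes the group mean beta and a one-sample
#' t-test per ROI x condition cell, with Benjamini-Hochberg adjustment across
#' all cells.
#'
#' @param betas Data frame with columns `subject`, `condition`, `roi`, `beta`
#'   and optionally `channel`.
#' @return Data frame with per-cell `mean_beta`, `se`, `t`, `p`, `p_fdr`,
#'   `n_subjects`.
#' @export
group_level <- function(betas) {
  needed <- c("subject", "condition", "roi", "beta")
  missing_cols <- setdiff(needed, names(betas))
  if (length(missing_cols)) {
    stop_config("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if ("channel" %in% names(betas)) {
    agg <- aggregate(beta ~ subject + condition + roi, data = betas, FUN = mean)
  } else {
    agg <- betas[, needed]
  }
  key <- interaction(agg$condition, agg$roi, drop = TRUE)
  rows <- lapply(split(agg, key), function(d) {
    if (nrow(d) < 2L) stop_config("cell %s/%s has fewer than 2 subjects",
                                  d$condition[1L], d$roi[1L])
    m <- mean(d$beta); s <- sd(d$beta) / sqrt(nrow(d))
    tstat <- if (s > 0) m / s else 0
    data.frame(condition = d$condition[1L], roi = d$roi[1L], mean_beta = m,
               se = s, t = tstat,
               p = 2 * pt(-abs(tstat), df = nrow(d) - 1L),
               n_subjects = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}
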