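# Lagged design for a VAR(p): response rows t = p+1..n, regressors are an
# intercept plus lags 1..p of every variable, ordered variable-major.
var_lagged_design <- function(x, p) {
  n <- nrow(x); k <- ncol(x)
  y <- x[(p + 1L):n, , drop = FALSE]
  lags <- matrix(0, n - p, k * p)
  cn <- character(k * p)
  for (j in seq_len(p)) {
    cols <- ((j - 1L) * k + 1L):(j * k)
    lags[, cols] <- x[(p + 1L - j):(n - j), , drop = FALSE]
    cn[cols] <- paste0(colnames(x), ".l", j)
  }
  colnames(lags) <- cn
  list(y = y, Z = cbind(intercept = rep(1, n - p), lags))
}

companion_radius <- function(A) {
  # A: list of p (k x k) lag-coefficient matrices
  p <- length(A); k <- nrow(A[[1L]])
  comp <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) comp[1:k, ((j - 1L) * k + 1L):(j * k)] <- A[[j]]
  if (p > 1L) comp[(k + 1L):(k * p), 1L:(k * (p - 1L))] <- diag(k * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Fit a vector autoregression with BIC order selection
#'
#' Per-equation least squares (conditional maximum likelihood under Gaussian
#' innovations) with the order chosen to minimize the multivariate BIC over
#' `1:max_order`, all candidate orders scored on the common sample that
#' excludes the first `max_order` observations. Stability (companion spectral
#' radius < 1) and residual whiteness (Ljung-Box per equation, lag 20) are
#' checked and recorded; instability of the selected model is an error.
#'
#' @param x Numeric matrix, time in rows, one column per ROI/variable.
#' @param max_order Largest order screened.
#' @param order Optional fixed order (skips selection).
#' @return List of class `var_model`: `order`, `A` (list of lag matrices),
#'   `intercept`, `sigma` (innovation covariance), `residuals`, `aic`, `bic`,
#'   `stable`, `spectral_radius`, `whiteness_p` (per equation), `n_effective`.
#' @export
fit_var <- function(x, max_order = 20L, order = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  n <- nrow(x); k <- ncol(x)
  if (n <= k * max_order + 10L) {
    stop_config("series too short for max_order %d with %d variables", max_order, k)
  }
  if (is.null(order)) {
    n_eff <- n - max_order
    bics <- vapply(seq_len(max_order), function(p) {
      ld <- var_lagged_design(x[(max_order - p + 1L):n, , drop = FALSE], p)
      fit <- lm.fit(ld$Z, ld$y)
      sig <- crossprod(as.matrix(fit$residuals)) / n_eff
      det_s <- det(sig)
      if (det_s <= 0) return(Inf)
      n_eff * log(det_s) + (k * (k * p + 1L)) * log(n_eff)
    }, numeric(1L))
    order <- which.min(bics)
  }
  p <- as.integer(order)
  ld <- var_lagged_design(x, p)
  if (qr(ld$Z)$rank < ncol(ld$Z)) stop_config("collinear lagged regressors")
  fit <- lm.fit(ld$Z, ld$y)
  B <- as.matrix(fit$coefficients)  # (1 + k*p) x k
  A <- lapply(seq_len(p), function(j) {
    t(B[1L + ((j - 1L) * k + 1L):(j * k), , drop = FALSE])
  })
  res <- as.matrix(fit$residuals)
  n_eff <- nrow(res)
  sigma <- crossprod(res) / n_eff
  radius <- companion_radius(A)
  if (radius >= 1) {
    stop_config("selected VAR(%d) is unstable (spectral radius %.3f); use a lower order or more data",
                p, radius)
  }
  npar <- k * (k * p + 1L)
  ll_term <- n_eff * log(max(det(sigma), 1e-300))
  white_lag <- min(20L, max(5L, n_eff %/% 5L))
  whiteness <- apply(res, 2L, function(e) {
    stats::Box.test(e, lag = white_lag, type = "Ljung-Box",
                    fitdf = min(p, white_lag - 1L))$p.value
  })
  structure(list(
    order = p, A = A, intercept = B[1L, ], sigma = sigma, residuals = res,
    aic = ll_term + 2 * npar, bic = ll_term + npar * log(n_eff),
    stable = TRUE, spectral_radius = radius,
    whiteness_p = whiteness, n_effective = n_eff, variables = colnames(x)
  ), class = "var_model")
}

#' Pairwise-conditional Granger causality over a set of ROI series
#'
#' For each directed pair (source -> target), compares the full VAR(p)
#' equation for the target against the reduced regression that omits the
#' source's lags while conditioning on all remaining variables' lags. The GC
#' magnitude is the log residual-variance ratio `ln(var_reduced/var_full)`;
#' significance uses the corresponding F-test with Benjamini-Hochberg
#' adjustment across all ordered pairs.
#'
#' @param x Numeric matrix, time x ROI.
#' @param max_order,order Passed to [fit_var()].
#' @param q FDR level for the significant edge set.
#' @return List of class `gc_result`: `gc`, `f_stat`, `p`, `p_fdr` (k x k
#'   matrices, diagonal `NA`), `significant` (logical matrix), `order`,
#'   `model` (the fitted [fit_var()] object), `edges` (long-format data
#'   frame).
#' @export
pairwise_conditional_gc <- function(x, max_order = 20L, order = NULL, q = 0.05) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  model <- fit_var(x, max_order = max_order, order = order)
  p <- model$order
  k <- ncol(x)
  ld <- var_lagged_design(x, p)
  n_eff <- nrow(ld$y)
  k_full <- ncol(ld$Z)
  full_fit <- lm.fit(ld$Z, ld$y)
  rss_full <- colSums(as.matrix(full_fit$residuals)^2)
  gc <- fstat <- pmat <- matrix(NA_real_, k, k,
                                dimnames = list(colnames(x), colnames(x)))
  lag_var <- rep(seq_len(k), times = p)  # variable index of each lag column
  for (i in seq_len(k)) {
    keep <- c(TRUE, lag_var != i)
    Zr <- ld$Z[, keep, drop = FALSE]
    red_fit <- lm.fit(Zr, ld$y)
    rss_red <- colSums(as.matrix(red_fit$residuals)^2)
    for (j in seq_len(k)) {
      if (i == j) next
      gc[i, j] <- log(rss_red[j] / rss_full[j])
      f <- ((rss_red[j] - rss_full[j]) / p) / (rss_full[j] / (n_eff - k_full))
      fstat[i, j] <- f
      pmat[i, j] <- pf(f, p, n_eff - k_full, lower.tail = FALSE)
    }
  }
  off <- !diag(k)
  p_fdr <- matrix(NA_real_, k, k, dimnames = dimnames(pmat))
  p_fdr[off] <- fdr_adjust(pmat[off])
  significant <- p_fdr < q
  idx <- which(off, arr.ind = TRUE)
  edges <- data.frame(
    from_roi = colnames(x)[idx[, 1L]], to_roi = colnames(x)[idx[, 2L]],
    gc = gc[off], f_stat = fstat[off], p = pmat[off], p_fdr = p_fdr[off],
    significant = significant[off], stringsAsFactors = FALSE
  )
  structure(list(gc = gc, f_stat = fstat, p = pmat, p_fdr = p_fdr,
                 significant = significant, order = p, q = q, model = model,
                 edges = edges),
            class = "gc_result")
}

#' Causal density of a Granger-causality network
#'
#' Unweighted causal density is the fraction of ordered ROI pairs whose edge
#' is significant after FDR correction (72 pairs for nine ROIs); weighted
#' causal density is the mean GC magnitude over all ordered pairs.
#'
#' @param gc A [pairwise_conditional_gc()] result.
#' @return List with `unweighted` and `weighted`.
#' @export
causal_density <- function(gc) {
  off <- !is.na(gc$gc)
  list(
    unweighted = mean(gc$significant[off]),
    weighted = mean(gc$gc[off])
  )
}
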