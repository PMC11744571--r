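# Fast OLS coefficient extraction used inside the bootstrap loop.
ols_paths <- function(X, M, Y, Z) {
  n <- length(X)
  one <- rep(1, n)
  Zm <- if (is.null(Z)) cbind(one) else cbind(one, Z)
  a <- .lm.fit(cbind(Zm, X), M)$coefficients
  full <- .lm.fit(cbind(Zm, X, M), Y)$coefficients
  tot <- .lm.fit(cbind(Zm, X), Y)$coefficients
  q <- ncol(Zm)
  c(a = a[q + 1L], b = full[q + 2L], c_prime = full[q + 1L], c = tot[q + 1L])
}

# Bias-corrected percentile interval (Efron): percentile bootstrap with the
# cutpoints shifted by the median-bias correction z0.
bc_ci <- function(boot, estimate, level = 0.95) {
  boot <- boot[is.finite(boot)]
  prop <- mean(boot < estimate)
  prop <- min(max(prop, 1 / (length(boot) + 1)), length(boot) / (length(boot) + 1))
  z0 <- qnorm(prop)
  alpha <- (1 - level) / 2
  probs <- pnorm(2 * z0 + qnorm(c(alpha, 1 - alpha)))
  unname(quantile(boot, probs = probs))
}

#' Covariate-adjusted three-variable linear mediation
#'
#' Fits the standard mediation triangle by three OLS regressions with an
#' identical covariate set Z: `M ~ X + Z` (path a), `Y ~ X + M + Z` (paths b
#' and c'), and `Y ~ X + Z` (total effect c). The indirect effect is `a * b`,
#' and the linear identity `c = c' + a * b` holds exactly by construction.
#' Inference for every path uses a bias-corrected percentile bootstrap with
#' subject-level case resampling (covariates resampled with their cases);
#' the mediation is declared significant when the indirect-effect CI excludes
#' zero.
#'
#' @param data Data frame with columns `x`, `m`, `y` (per-subject change
#'   scores) and, when `covariates = TRUE`, `sex`, `age`, `bmi`.
#' @param covariates Adjust for sex/age/BMI.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Seed for the resampling.
#' @param level CI level.
#' @return List of class `mediation_result`: `paths` (data frame with
#'   estimate, SE, t, p, and bootstrap CI per path: a, b, c_prime, c,
#'   indirect), `significant` (indirect CI excludes zero), `n`, `n_boot`,
#'   `covariates`, `seed`.
#' @export
fit_mediation <- function(data, covariates = TRUE, n_boot = 10000L,
                          seed = 1L, level = 0.95) {
  needed <- c("x", "m", "y", if (covariates) c("sex", "age", "bmi"))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop_config("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  keep <- complete.cases(data[, needed])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 10L) stop_config("at least 10 complete cases are required (have %d)", n)
  Z <- if (covariates) {
    z <- as.matrix(d[, c("sex", "age", "bmi")])
    storage.mode(z) <- "double"
    z
  } else NULL
  if (!is.null(Z) && qr(cbind(1, Z, d$x, d$m))$rank < 3L + ncol(Z)) {
    stop_config("perfect collinearity among predictors")
  }

  est <- ols_paths(d$x, d$m, d$y, Z)
  est <- c(est, indirect = unname(est["a"] * est["b"]))

  # classical per-path SE/t/p from the lm fits
  lm_a <- if (covariates) lm(m ~ x + sex + age + bmi, data = d) else lm(m ~ x, data = d)
  lm_f <- if (covariates) lm(y ~ x + m + sex + age + bmi, data = d) else lm(y ~ x + m, data = d)
  lm_t <- if (covariates) lm(y ~ x + sex + age + bmi, data = d) else lm(y ~ x, data = d)
  pick <- function(fit, term) summary(fit)$coefficients[term, c(1, 2, 3, 4)]
  cls <- rbind(a = pick(lm_a, "x"), b = pick(lm_f, "m"),
               c_prime = pick(lm_f, "x"), c = pick(lm_t, "x"))
  se_ind <- sqrt(cls["a", 2]^2 * est["b"]^2 + cls["b", 2]^2 * est["a"]^2)
  cls <- rbind(cls, indirect = c(est["indirect"], se_ind,
                                 est["indirect"] / se_ind,
                                 2 * pnorm(-abs(est["indirect"] / se_ind))))

  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 5L,
                 dimnames = list(NULL, c("a", "b", "c_prime", "c", "indirect")))
  for (bix in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Zb <- if (is.null(Z)) NULL else Z[idx, , drop = FALSE]
    pb <- try(ols_paths(d$x[idx], d$m[idx], d$y[idx], Zb), silent = TRUE)
    if (!inherits(pb, "try-error") && all(is.finite(pb))) {
      boot[bix, 1:4] <- pb
      boot[bix, 5L] <- pb["a"] * pb["b"]
    }
  }
  ci <- t(vapply(colnames(boot), function(nm) bc_ci(boot[, nm], est[[nm]], level),
                 numeric(2L)))
  paths <- data.frame(
    path = rownames(cls), estimate = unname(est[rownames(cls)]),
    se = unname(cls[, 2]), t = unname(cls[, 3]), p = unname(cls[, 4]),
    ci_lower = ci[rownames(cls), 1L], ci_upper = ci[rownames(cls), 2L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    paths = paths,
    significant = paths$ci_lower[paths$path == "indirect"] > 0 ||
      paths$ci_upper[paths$path == "indirect"] < 0,
    n = n, n_dropped = n_dropped, n_boot = n_boot,
    covariates = covariates, seed = seed
  ), class = "mediation_result")
}

#' Screen candidate mediation variables by partial correlation
#'
#' Pairwise partial correlations between all candidate columns, controlling
#' for sex/age/BMI by residualization, with t-based p-values and FDR
#' adjustment across pairs. Constant columns are dropped with a warning.
#'
#' @param data Data frame; candidate variables are every column except the
#'   covariates.
#' @param covariates Covariate column names to partial out (present in
#'   `data`; use `character(0)` for marginal correlations).
#' @return Data frame with `var1`, `var2`, `r`, `p`, `p_fdr`, `flagged`
#'   (significant after FDR at 0.05).
#' @export
screen_correlations <- function(data, covariates = c("sex", "age", "bmi")) {
  vars <- setdiff(names(data), covariates)
  if (length(vars) < 3L) stop_config("at least 3 candidate variables are required")
  keep <- complete.cases(data)
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 5L) stop_config("at least 5 complete cases are required")
  constant <- vars[vapply(vars, function(v) sd(d[[v]]) == 0, logical(1L))]
  if (length(constant)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(constant, collapse = ", ")), call. = FALSE)
    vars <- setdiff(vars, constant)
  }
  q <- length(covariates)
  res <- sapply(vars, function(v) {
    if (q == 0L) return(d[[v]] - mean(d[[v]]))
    resid(lm(as.formula(paste(v, "~", paste(covariates, collapse = "+"))), data = d))
  })
  prs <- utils::combn(vars, 2L, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    r <- cor(res[, pr[1L]], res[, pr[2L]])
    df <- n - 2L - q
    tstat <- r * sqrt(df / (1 - r^2))
    data.frame(var1 = pr[1L], var2 = pr[2L], r = r,
               p = 2 * pt(-abs(tstat), df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  out$flagged <- out$p_fdr < 0.05
  out
}
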