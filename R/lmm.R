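#' Specify the study's linear mixed model for one outcome
#'
#' Fixed effects are the condition x timepoint interaction (optionally
#' crossed with Stroop block) plus the sex/age/BMI covariates; the random
#' structure is a per-participant intercept; estimation is maximum
#' likelihood. Treatment coding with the stated reference levels (control
#' condition, pre-intervention, baseline block) makes the interaction
#' coefficient of a two-condition design equal to the post-pre
#' difference-in-differences.
#'
#' @param outcome Name of the outcome column.
#' @param include_block Include the three-way condition x timepoint x block
#'   structure.
#' @param covariates Covariate column names (default sex, age, bmi; use
#'   `character(0)` for none).
#' @param ref_condition,ref_timepoint,ref_block Reference levels.
#' @return List of class `lmm_spec`.
#' @export
lmm_spec <- function(outcome, include_block = FALSE,
                     covariates = c("sex", "age", "bmi"),
                     ref_condition = "SIT", ref_timepoint = "pre",
                     ref_block = "baseline") {
  structure(list(outcome = outcome, include_block = include_block,
                 covariates = covariates, ref_condition = ref_condition,
                 ref_timepoint = ref_timepoint, ref_block = ref_block),
            class = "lmm_spec")
}

#' Fit the study linear mixed model
#'
#' Maximum-likelihood fit (lmerTest, Satterthwaite degrees of freedom for the
#' coefficient t-tests) of the [lmm_spec()] model.
#'
#' @param spec An [lmm_spec()] object.
#' @param data Tidy data frame with `subject`, `condition`, `timepoint`,
#'   optionally `block`, the covariates, and the outcome column.
#' @return List of class `lmm_fit`: `model` (the `lmerModLmerTest` object),
#'   `coefficients` (data frame with beta, SE, df, t, p), `aic`, `bic`,
#'   `varcomp` (random-intercept and residual variances), `singular`, `spec`,
#'   `data`.
#' @export
fit_lmm <- function(spec, data) {
  needed <- c("subject", "condition", "timepoint", spec$outcome, spec$covariates,
              if (spec$include_block) "block")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop_config("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  d <- data
  d$condition <- stats::relevel(factor(d$condition), ref = spec$ref_condition)
  d$timepoint <- stats::relevel(factor(d$timepoint), ref = spec$ref_timepoint)
  if (spec$include_block) d$block <- stats::relevel(factor(d$block), ref = spec$ref_block)
  d <- d[is.finite(d[[spec$outcome]]), , drop = FALSE]
  fixed <- if (spec$include_block) "condition * timepoint * block" else
    "condition * timepoint"
  if (length(spec$covariates)) {
    fixed <- paste(fixed, "+", paste(spec$covariates, collapse = " + "))
  }
  form <- as.formula(paste(spec$outcome, "~", fixed, "+ (1 | subject)"))
  model <- lmerTest::lmer(form, data = d, REML = FALSE,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
  smry <- summary(model)$coefficients
  coefs <- data.frame(term = rownames(smry), beta = smry[, "Estimate"],
                      se = smry[, "Std. Error"], df = smry[, "df"],
                      t = smry[, "t value"], p = smry[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(list(
    model = model, coefficients = coefs,
    aic = stats::AIC(model), bic = stats::BIC(model),
    varcomp = setNames(vc$vcov, vc$grp),
    singular = lme4::isSingular(model), spec = spec, data = d
  ), class = "lmm_fit")
}

#' Difference-in-differences contrasts from estimated marginal means
#'
#' Computes the model-implied condition x timepoint cell means averaged over
#' covariates (and block, when present), then forms the post-pre
#' difference-in-differences for every non-reference condition against the
#' reference, plus all pairwise condition DiDs, with FDR adjustment within
#' the family.
#'
#' @param fit An [fit_lmm()] result.
#' @return Data frame with `contrast`, `estimate`, `se`, `df`, `t`, `p`,
#'   `p_fdr`.
#' @export
emmeans_contrasts <- function(fit) {
  emm <- emmeans::emmeans(fit$model, ~ condition * timepoint,
                          lmer.df = "satterthwaite")
  grid <- as.data.frame(emm)[, c("condition", "timepoint")]
  conds <- levels(grid$condition)
  post <- levels(factor(fit$data$timepoint))
  post <- setdiff(post, fit$spec$ref_timepoint)[1L]
  pairs_idx <- utils::combn(conds, 2L, simplify = FALSE)
  contrasts <- lapply(pairs_idx, function(pr) {
    w <- numeric(nrow(grid))
    # (post - pre | pr[2]) - (post - pre | pr[1])
    w[grid$condition == pr[2L] & grid$timepoint == post] <- 1
    w[grid$condition == pr[2L] & grid$timepoint == fit$spec$ref_timepoint] <- -1
    w[grid$condition == pr[1L] & grid$timepoint == post] <- -1
    w[grid$condition == pr[1L] & grid$timepoint == fit$spec$ref_timepoint] <- 1
    w
  })
  names(contrasts) <- vapply(pairs_idx, function(pr)
    sprintf("(%s-%s) post-pre DiD", pr[2L], pr[1L]), character(1L))
  ct <- as.data.frame(emmeans::contrast(emm, method = contrasts))
  out <- data.frame(contrast = ct$contrast, estimate = ct$estimate,
                    se = ct$SE, df = ct$df, t = ct$t.ratio, p = ct$p.value,
                    stringsAsFactors = FALSE)
  out$p_fdr <- fdr_adjust(out$p)
  out
}

# Durbin-Watson statistic on residuals ordered within subject, with the
# common normal approximation DW ~ 2(1 - r1) for the p-value.
durbin_watson <- function(residuals, subject) {
  o <- order(subject)
  e <- residuals[o]; s <- subject[o]
  same <- s[-1L] == s[-length(s)]
  d <- sum((e[-1L][same] - e[-length(e)][same])^2) / sum(e^2)
  n <- sum(same)
  r1 <- 1 - d / 2
  z <- r1 * sqrt(n)
  list(statistic = d, p = 2 * pnorm(-abs(z)))
}

#' Assumption diagnostics with automatic remediation
#'
#' Runs the Shapiro-Wilk test on the model residuals (subsampled at 5000 when
#' longer), the Breusch-Pagan test of residuals against fitted values, and a
#' Durbin-Watson check on within-subject residual ordering. If normality or
#' homoscedasticity fail at `alpha`, the outcome is refit under a
#' variance-stabilizing transform (log when strictly positive, otherwise a
#' rank-based inverse-normal transform); if the transformed fit still fails,
#' subject-level case-resampling bootstrap confidence intervals for the fixed
#' effects are computed. The remediation path taken is recorded.
#'
#' @param fit An [fit_lmm()] result.
#' @param alpha Diagnostic significance level.
#' @param n_boot Bootstrap resamples for the fallback (subject-level case
#'   resampling).
#' @param seed Seed for the bootstrap stage.
#' @return List with `shapiro_p`, `breusch_pagan_p`, `durbin_watson`
#'   (statistic and p), `remediation` (`"none"`, `"transformed"` or
#'   `"bootstrapped"`), `fit` (possibly refit), and `boot_ci` (fixed-effect
#'   percentile CIs) when bootstrapped.
#' @export
check_assumptions <- function(fit, alpha = 0.05, n_boot = 2000L, seed = 1L) {
  diagnose <- function(f) {
    e <- resid(f$model)
    es <- if (length(e) > 5000L) {
      set.seed(seed); sample(e, 5000L)
    } else e
    sw <- shapiro.test(es)$p.value
    bp <- lmtest::bptest(lm(e ~ fitted(f$model)))$p.value
    dw <- durbin_watson(e, f$data$subject)
    list(shapiro_p = sw, breusch_pagan_p = bp, durbin_watson = dw,
         fails = sw < alpha || bp < alpha)
  }
  d0 <- diagnose(fit)
  remediation <- "none"
  out_fit <- fit
  diag_final <- d0
  if (d0$fails) {
    y <- fit$data[[fit$spec$outcome]]
    newdata <- fit$data
    newdata[[fit$spec$outcome]] <- if (all(y > 0)) log(y) else
      qnorm((rank(y) - 0.5) / length(y))
    out_fit <- fit_lmm(fit$spec, newdata)
    remediation <- "transformed"
    diag_final <- diagnose(out_fit)
    if (diag_final$fails) {
      remediation <- "bootstrapped"
    }
  }
  boot_ci <- NULL
  if (remediation == "bootstrapped") {
    set.seed(seed)
    subjects <- unique(fit$data$subject)
    terms <- fit$coefficients$term
    mat <- matrix(NA_real_, n_boot, length(terms))
    for (b in seq_len(n_boot)) {
      pick <- sample(subjects, length(subjects), replace = TRUE)
      dd <- do.call(rbind, lapply(seq_along(pick), function(i) {
        di <- fit$data[fit$data$subject == pick[i], , drop = FALSE]
        di$subject <- paste0("bs", i)
        di
      }))
      fb <- try(suppressWarnings(suppressMessages(fit_lmm(fit$spec, dd))), silent = TRUE)
      if (!inherits(fb, "try-error")) {
        mat[b, ] <- fb$coefficients$beta[match(terms, fb$coefficients$term)]
      }
    }
    boot_ci <- data.frame(
      term = terms,
      lower = apply(mat, 2L, quantile, probs = 0.025, na.rm = TRUE),
      upper = apply(mat, 2L, quantile, probs = 0.975, na.rm = TRUE),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  list(shapiro_p = diag_final$shapiro_p,
       breusch_pagan_p = diag_final$breusch_pagan_p,
       durbin_watson = diag_final$durbin_watson,
       remediation = remediation, fit = out_fit, boot_ci = boot_ci)
}
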