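#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom sd var coef resid fitted lm lm.fit
#'   .lm.fit pnorm qnorm pf pt shapiro.test p.adjust aov quantile aggregate
#'   complete.cases convolve dgamma cor setNames as.formula vcov dbinom
#'   AIC BIC
#' @importFrom utils head tail read.csv write.csv
NULL

# Counter-based seed stream: derives a child seed from a master seed and an
# index so per-unit regeneration is independent of ordering. Kept below 2^31.
child_seed <- function(master, index, salt = 0L) {
  master <- as.double(master)
  s <- (master * 48271 + index * 16807 + salt * 69621) %% 2147483629
  as.integer(s %% 2147483587) + 1L
}

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_config("'%s' must be finite and > 0", name)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_config("'%s' must be TRUE or FALSE", name)
  }
  invisible(x)
}

# Benjamini-Hochberg wrapper used across modules so the adjustment is applied
# identically everywhere (edges, ROIs, contrasts, correlation screens).
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")
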