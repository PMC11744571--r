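#' Score one cell of dual-task Stroop trials
#'
#' Summarizes all trials of one subject x condition x timepoint x block cell:
#' mean reaction time over correct trials only, error rate (errors / total
#' trials, omissions counted as errors), and the inverse efficiency score
#' IES = mean correct RT / (1 - error rate), which penalizes speed-accuracy
#' trade-offs (higher = less efficient).
#'
#' @param rt_ms Numeric vector of per-trial reaction times in milliseconds
#'   (`NA` for omitted responses).
#' @param correct Logical vector, `TRUE` for correct responses.
#' @return List with `mean_rt_correct_ms`, `error_rate`, `ies_ms`, `n_trials`,
#'   `n_correct`, and flags `undefined_rt` (no correct trials) and
#'   `infinite_ies` (error rate 1).
#' @examples
#' summarize_cell(c(500, 520, 480), c(TRUE, TRUE, FALSE))
#' @export
summarize_cell <- function(rt_ms, correct) {
  if (length(rt_ms) != length(correct) || length(rt_ms) == 0L) {
    stop_config("'rt_ms' and 'correct' must be equal-length, non-empty vectors")
  }
  correct <- as.logical(correct)
  n <- length(correct)
  n_correct <- sum(correct)
  er <- (n - n_correct) / n
  mean_rt <- if (n_correct > 0L) mean(rt_ms[correct]) else NA_real_
  ies <- if (n_correct > 0L && er < 1) mean_rt / (1 - er) else NA_real_
  list(
    mean_rt_correct_ms = mean_rt, error_rate = er, ies_ms = ies,
    n_trials = n, n_correct = n_correct,
    undefined_rt = n_correct == 0L, infinite_ies = er >= 1
  )
}

#' Summarize a trial table into per-cell behavioral measures
#'
#' @param trials Data frame with columns `subject`, `condition`, `timepoint`,
#'   `block`, `rt_ms`, `correct`.
#' @return Data frame, one row per cell, with the [summarize_cell()] measures.
#' @export
summarize_trials <- function(trials) {
  needed <- c("subject", "condition", "timepoint", "block", "rt_ms", "correct")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop_config("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  key <- interaction(trials$subject, trials$condition, trials$timepoint,
                     trials$block, drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    s <- summarize_cell(d$rt_ms, d$correct)
    data.frame(
      subject = d$subject[1L], condition = d$condition[1L],
      timepoint = d$timepoint[1L], block = d$block[1L],
      mean_rt_correct_ms = s$mean_rt_correct_ms, error_rate = s$error_rate,
      ies_ms = s$ies_ms, n_trials = s$n_trials, n_correct = s$n_correct,
      undefined_rt = s$undefined_rt, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' z-score behavioral measures against a normalization pool
#'
#' Normalizes RT, error rate and IES as z = (x - pool mean) / pool SD. The
#' default pool is all subjects' pre-intervention cells, per measure and per
#' Stroop block, applied to both timepoints, so post-intervention change is
#' expressed on a stable baseline scale. Alternative pools: `"global"` (all
#' cells) and `"per_condition"` (pre cells within each condition).
#'
#' @param summaries Output of [summarize_trials()].
#' @param pool One of `"pre"`, `"global"`, `"per_condition"`.
#' @param pre_level Label identifying the pre-intervention timepoint.
#' @return `summaries` with added columns `z_rt`, `z_er`, `z_ies`.
#' @export
zscore_measures <- function(summaries, pool = c("pre", "global", "per_condition"),
                            pre_level = "pre") {
  pool <- match.arg(pool)
  measures <- c(mean_rt_correct_ms = "z_rt", error_rate = "z_er", ies_ms = "z_ies")
  out <- summaries
  pool_key <- switch(pool,
    pre = ,
    global = factor(summaries$block),
    per_condition = interaction(summaries$block, summaries$condition, drop = TRUE)
  )
  in_pool <- if (pool == "global") rep(TRUE, nrow(summaries)) else
    summaries$timepoint == pre_level
  if (!any(in_pool)) stop_config("normalization pool '%s' selected no cells", pool)
  for (m in names(measures)) {
    z <- rep(NA_real_, nrow(summaries))
    for (g in levels(pool_key)) {
      sel <- pool_key == g
      ref <- summaries[[m]][sel & in_pool]
      ref <- ref[is.finite(ref)]
      if (length(ref) < 2L || sd(ref) == 0) {
        stop_config("degenerate normalization pool for '%s' in group '%s'", m, g)
      }
      z[sel] <- (summaries[[m]][sel] - mean(ref)) / sd(ref)
    }
    out[[measures[[m]]]] <- z
  }
  out
}
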