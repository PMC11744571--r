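#' Branching constants for the revised Knudtson vessel summarization
#'
#' Branching coefficients linking parent trunk retinal vessels with their
#' branches: 0.88 for arterioles and 0.95 for venules.
#'
#' @return Named list with `k_arteriole` and `k_venule`.
#' @export
branching_constants <- function() {
  list(k_arteriole = 0.88, k_venule = 0.95)
}

#' Combine two vessel widths into a parent-trunk equivalent
#'
#' The revised Knudtson formula for the caliber of the parent trunk implied by
#' two branch widths: `k * sqrt(w1^2 + w2^2)`.
#'
#' @param w1,w2 Branch widths in micrometres (> 0).
#' @param k Branching coefficient in (0, 1]; 0.88 for arterioles, 0.95 for
#'   venules.
#' @return Parent equivalent width (micrometres).
#' @examples
#' pair_equivalent(10, 10, 0.88)
#' @export
pair_equivalent <- function(w1, w2, k) {
  check_positive(w1, "w1")
  check_positive(w2, "w2")
  check_positive(k, "k")
  k * sqrt(w1^2 + w2^2)
}

#' Iteratively reduce a set of vessel widths to a central equivalent
#'
#' Each round sorts the current widths, pairs the largest with the smallest
#' via [pair_equivalent()], carries the median element forward unpaired when
#' the count is odd, and repeats until a single central equivalent remains.
#' A single width is returned unchanged.
#'
#' @param widths Numeric vector of positive widths (micrometres).
#' @param k Branching coefficient.
#' @return Central vessel equivalent (micrometres).
#' @examples
#' iterative_reduce(rep(10, 6), 0.88)
#' @export
iterative_reduce <- function(widths, k) {
  if (length(widths) == 0L) stop_config("'widths' must contain at least one value")
  check_positive(widths, "widths")
  check_positive(k, "k")
  w <- as.numeric(widths)
  while (length(w) > 1L) {
    w <- sort(w)
    n <- length(w)
    half <- n %/% 2L
    paired <- pair_equivalent(w[seq_len(half)], w[n + 1L - seq_len(half)], k)
    w <- if (n %% 2L == 1L) c(paired, w[half + 1L]) else paired
  }
  w
}

#' Compute CRAE, CRVE and the arteriole-to-venule ratio
#'
#' Reduces the measured arteriole and venule widths (standard input: the six
#' largest of each) to the central retinal arteriolar equivalent (CRAE, k =
#' 0.88) and central retinal venular equivalent (CRVE, k = 0.95), and forms
#' their ratio. The standard arteriole-to-venule ratio is CRAE/CRVE; the
#' `paper_literal` convention (CRVE/CRAE) is selectable, and the convention
#' used is recorded in the result so downstream tables stay auditable.
#'
#' @param arteriole_widths,venule_widths Positive widths in micrometres.
#' @param convention `"standard"` (CRAE/CRVE, default) or `"paper_literal"`
#'   (CRVE/CRAE).
#' @return List of class `retinal_indices` with `crae`, `crve`, `avr`,
#'   `avr_convention` and `quality_flag` (`TRUE` when fewer than six vessels
#'   were supplied on either side).
#' @examples
#' compute_indices(rep(10, 6), rep(10, 6))
#' @export
compute_indices <- function(arteriole_widths, venule_widths,
                            convention = c("standard", "paper_literal")) {
  convention <- match.arg(convention)
  if (length(arteriole_widths) == 0L || length(venule_widths) == 0L) {
    stop_config("incomplete measurement: both arteriole and venule widths are required")
  }
  kc <- branching_constants()
  crae <- iterative_reduce(arteriole_widths, kc$k_arteriole)
  crve <- iterative_reduce(venule_widths, kc$k_venule)
  avr <- if (convention == "standard") crae / crve else crve / crae
  structure(
    list(
      crae = crae, crve = crve, avr = avr, avr_convention = convention,
      quality_flag = length(arteriole_widths) < 6L || length(venule_widths) < 6L
    ),
    class = "retinal_indices"
  )
}

#' Batch retinal indices from a long vessel-width table
#'
#' @param widths Data frame with columns `subject`, `condition`, `timepoint`,
#'   `vessel_type` (`"arteriole"`/`"venule"`) and `width_um`.
#' @param convention Passed to [compute_indices()].
#' @return Data frame with one row per subject/condition/timepoint carrying
#'   `crae`, `crve`, `avr`, `avr_convention` and `quality_flag`.
#' @export
retinal_indices_table <- function(widths, convention = "standard") {
  needed <- c("subject", "condition", "timepoint", "vessel_type", "width_um")
  missing_cols <- setdiff(needed, names(widths))
  if (length(missing_cols)) {
    stop_config("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  key <- interaction(widths$subject, widths$condition, widths$timepoint, drop = TRUE)
  out <- lapply(split(widths, key), function(d) {
    idx <- compute_indices(
      d$width_um[d$vessel_type == "arteriole"],
      d$width_um[d$vessel_type == "venule"],
      convention = convention
    )
    data.frame(
      subject = d$subject[1L], condition = d$condition[1L],
      timepoint = d$timepoint[1L],
      crae = idx$crae, crve = idx$crve, avr = idx$avr,
      avr_convention = idx$avr_convention, quality_flag = idx$quality_flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Single-measure absolute-agreement intraclass correlation
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC -- ICC(A,1)
#' in the McGraw and Wong taxonomy -- computed from the two-way ANOVA mean
#' squares. Used to quantify grader reproducibility of the retinal indices.
#'
#' @param replicates Numeric matrix, subjects in rows, replicate gradings in
#'   columns (>= 2 columns).
#' @return ICC estimate in \[-1, 1\].
#' @export
icc_reproducibility <- function(replicates) {
  replicates <- as.matrix(replicates)
  if (ncol(replicates) < 2L) stop_config("at least 2 replicates per subject are required")
  if (anyNA(replicates)) stop_config("replicate table must be complete")
  n <- nrow(replicates)
  k <- ncol(replicates)
  d <- data.frame(
    y = as.vector(replicates),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(aov(y ~ subject + rater, data = d))[[1L]][, "Mean Sq"]
  msr <- ms[[1L]]; msc <- ms[[2L]]; mse <- ms[[3L]]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
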