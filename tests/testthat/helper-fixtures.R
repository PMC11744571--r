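# Shared fixtures, all built in code at test time.

# Independent brute-force evaluation of the largest-with-smallest pairing
# rule, written without reusing the package's reduction loop.
brute_reduce <- function(widths, k) {
  w <- sort(as.numeric(widths))
  while (length(w) > 1L) {
    nxt <- c()
    while (length(w) >= 2L) {
      nxt <- c(nxt, k * sqrt(w[1L]^2 + w[length(w)]^2))
      w <- w[-c(1L, length(w))]
    }
    if (length(w) == 1L) nxt <- c(nxt, w)
    w <- sort(nxt)
  }
  w
}

# Minimal two-node VAR(1) truth with a single x -> y coupling.
two_node_truth <- function(coupling = 0.5, self = 0) {
  A <- matrix(c(self, 0, coupling, self), 2L, 2L, byrow = TRUE)
  var_ground_truth(2L, 1L, A, innovation_sd = 1)
}

# Stable 9-node VAR(1) truth matching the packaged montage, with a few
# planted directed couplings.
nine_node_truth <- function(weight = 0.35) {
  A <- diag(0.3, 9L)
  planted <- rbind(c(1, 3), c(4, 7), c(2, 9), c(5, 6))
  for (r in seq_len(nrow(planted))) A[planted[r, 2L], planted[r, 1L]] <- weight
  truth <- var_ground_truth(9L, 1L, A, innovation_sd = 1)
  attr(truth, "planted") <- planted
  truth
}

# Tiny deterministic trial table: n trials, first n_err incorrect.
toy_trials <- function(rt, n_err) {
  n <- length(rt)
  data.frame(
    subject = "S1", condition = "SIT", timepoint = "pre", block = "baseline",
    rt_ms = rt, correct = c(rep(FALSE, n_err), rep(TRUE, n - n_err))
  )
}

# Small profile for fast study-level tests: fewer subjects, same structure.
small_profile <- function(n_subjects = 12L) {
  p <- paper_effects()
  p$n_subjects <- as.integer(n_subjects)
  p
}
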