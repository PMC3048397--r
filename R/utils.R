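# Internal numerical helpers.

# log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Population standard deviation (divide by N, not N - 1). Both the observed
# width sigma_O and the width of model draws use this convention so that the
# ratio sigma_O / sigma_M compares like with like.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(max(mean(x * x) - m * m, 0))
}

# Set the global RNG deterministically when a seed is supplied; otherwise
# leave the caller's RNG state alone.
set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Deterministic per-item seed derived from a master seed and a label, so
# survey runs are reproducible item-by-item regardless of processing order.
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(master) + h) %% 2147483587)
}
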