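#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation so each stochastic component (generator,
# learner x fold, permutation explainer) can be reproduced in isolation from
# one global seed.  Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (o in offsets) {
    # small multiplier keeps the arithmetic exact in doubles (< 2^53)
    s <- (s * 48271 + as.numeric(o) + 1) %% 2147483647
  }
  as.integer(s)
}

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample standard deviation (ddof = 1), NA-safe length check
sample_sd <- function(x) stats::sd(x)
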