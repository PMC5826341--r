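# internal helpers shared across modules

# z-score a numeric vector; a constant column cannot be standardized and is
# the caller's signal for a degenerate predictor
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(structure(rep(NA_real_, length(x)), degenerate = TRUE))
  }
  (x - mean(x)) / s
}

is_degenerate <- function(x) isTRUE(attr(x, "degenerate")) || all(is.na(x))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  check_finite_scalar(x, name)
  if (x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer regardless of the user's base seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}
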