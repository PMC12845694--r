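# Internal helpers shared across modules.

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed for a named pipeline stage, derived from a global seed.
# Keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% 2147483587L
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be >= 0.", name))
  }
  invisible(x)
}

# Population standard deviation (divisor n), the convention used by the
# irregularity indices and error summaries.
pop_sd <- function(x) {
  n <- length(x)
  if (n < 1L) {
    return(NA_real_)
  }
  sqrt(sum((x - mean(x))^2) / n)
}
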