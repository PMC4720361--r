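# Internal helpers shared across modules.

# Run `expr` under a fixed seed when one is given, otherwise use the current
# RNG stream. Seeded calls never disturb the caller's RNG state.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Draw a child seed from the current RNG stream (kept below 2^31 - 1 so it is
# always a valid R integer seed).
child_seed <- function() {
  sample.int(.Machine$integer.max - 1L, 1L)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                 name, min, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.integer(x)
}

# "6/49 (0.122)" style dual notation used in human-readable reports when the
# probability is an exact rational over a known denominator.
format_prob <- function(p, denom = NULL) {
  if (!is.null(denom)) {
    num <- p * denom
    if (abs(num - round(num)) < 1e-9) {
      return(sprintf("%d/%d (%.3f)", as.integer(round(num)), as.integer(denom), p))
    }
  }
  sprintf("%.3f", p)
}
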