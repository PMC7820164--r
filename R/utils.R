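# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage counter.
# Keeps results in [1, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(master)) %% m)
  as.integer(1 + (s * 48271 + 7919 * as.numeric(counter)) %% (m - 1))
}

# Run `code` under a given seed without disturbing the caller's RNG stream.
# A NULL seed runs the code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Midpoints of the distance bins delimited by `breaks`.
bin_centers <- function(breaks) (breaks[-length(breaks)] + breaks[-1]) / 2
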