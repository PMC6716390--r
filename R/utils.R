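# Internal helpers shared across modules.

abort_config <- function(msg) stop(msg, call. = FALSE)

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed != round(seed))
    abort_config("`seed` must be a single integer")
  as.integer(seed)
}

# Derive a stream-specific seed from a master seed. Keeps results below
# .Machine$integer.max so derived seeds stay valid 32-bit integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(check_seed(seed))
  expr
}

is_simplex <- function(p, tol = 1e-8) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) && abs(sum(p) - 1) < tol
}

# Sample standard deviation of the non-missing values; NA if fewer than 2.
obs_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x)
}
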