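# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. All user-facing stochastic entry points funnel through
# this so that a single integer seed reproduces a result bit-for-bit.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    stop("a non-missing integer `seed` is required for reproducibility",
         call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stream index; stays within
# 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer(((as.double(seed) %% 1000003 + 1) * 9973 + as.double(i)) %%
               2147483629) + 1L
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
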