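# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no re-seeding).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Canonical unordered-pair key, used to join pair tables.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Nearest-rank order statistic: the ceiling(q * n)-th smallest value,
# clamped to [1, n].  q = 1 gives the maximum, q -> 0 the minimum.
nearest_rank <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  idx <- min(n, max(1L, as.integer(ceiling(q * n))))
  x[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
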