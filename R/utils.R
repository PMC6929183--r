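# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Each stochastic operation takes exactly one
# seed and records it in its output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
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
  force(expr)
}

# log(sum(exp(x))) without overflow; returns -Inf for empty/all -Inf input.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  }
  out
}

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

is_power_of_two <- function(p) {
  is_count(p, 1L) && bitwAnd(as.integer(p), as.integer(p) - 1L) == 0L
}
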