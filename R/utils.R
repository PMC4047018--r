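# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Row-wise log(sum(exp(m))) guarded against underflow.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)
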