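## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_quo2 <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_vec = FALSE) {
  if (!is.numeric(x) || (!allow_vec && length(x) != 1L))
    stop_quo2("'%s' must be a numeric %s", name,
              if (allow_vec) "vector" else "scalar")
  if (any(!is.finite(x)) || any(x < lower) || any(x > upper))
    stop_quo2("'%s' must be finite and in [%g, %g]", name, lower, upper)
  invisible(x)
}

## Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
## RNG stream is untouched. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## centered rolling mean, window in samples; edges use the available samples
roll_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
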