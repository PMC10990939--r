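# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so that package functions never clobber the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation: keeps all draws a pure function of the
# top-level seed while remaining inside 32-bit integer range
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.numeric(seed)
  for (o in offs) s <- (s * 48271 + o) %% 2147483647
  as.integer(s)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) {
    stop(sprintf("'%s' = %g outside allowed range [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
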