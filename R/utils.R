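# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' All stochastic stages consume one master seed and derive deterministic
#' per-stream children, so that e.g. the sigma-estimation segment and the
#' production run of an OPES simulation use independent but reproducible
#' streams.  The result stays below 2^31 - 1.
#'
#' @param seed master seed (non-negative integer-valued scalar)
#' @param stream small integer identifying the consumer stream
#' @return an integer-valued seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, stream = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(seed) %% 2147483629) + stream * 1000003
  as.integer(s %% 2147483629 + 1)
}

# run `expr` with R's RNG seeded locally, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

# trapezoid rule on possibly non-uniform grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
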