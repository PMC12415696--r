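abort <- function(...) stop(..., call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the prior
#' RNG state, so seeded rendering helpers do not disturb a caller's random
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-tile seed, kept within the 32-bit integer range.
derive_seed <- function(seed, a, b = 0L) {
  s <- (as.double(seed) * 48271 + as.double(a) * 100003 + as.double(b) * 7919) %% 2147483629
  as.integer(s) + 1L
}

# round-half-up, used wherever an 8-bit value is produced from a real one
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
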