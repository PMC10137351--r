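# Internal helpers: seed stream derivation and scoped RNG state.

#' Derive an independent sub-seed from a master seed and a stream label
#'
#' Each stochastic stage (surrogate noise, outer train/test split, inner
#' fit/select split) draws from its own stream so that changing one stage
#' never perturbs another's draws. The derivation is a simple deterministic
#' hash kept inside the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed master integer seed.
#' @param stream character label of the stage.
#' @return an integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# stop() with call. = FALSE everywhere for clean CLI-facing messages
abort <- function(...) stop(..., call. = FALSE)
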