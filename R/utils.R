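#' Derive a stage-specific child seed from a global seed
#'
#' Pipeline stages draw their random numbers from seeds derived
#' deterministically from one global seed and the stage name, so any stage can
#' be reproduced in isolation without replaying the stages before it.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  # Lehmer-style mix; doubles are exact well past 2^31 * 48271 / 2^31 steps
  x <- (abs(seed) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  as.integer((x + h) %% 2147483646 + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Small deterministic content hash (FNV-1a over the deparsed object),
# used to stamp output files with the configuration they came from.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
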