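#' Derive a reproducible substream seed
#'
#' Combines a master seed with one or more stream indices into a new 31-bit
#' seed via a multiplicative hash. Used so that every repetition, experiment
#' arm, and generator stage draws from an independent, reproducible stream.
#'
#' @param master integer master seed.
#' @param ... integer stream indices (repetition number, arm index, ...).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- (abs(master) %% m)
  for (v in c(...)) {
    stopifnot(is.numeric(v), is.finite(v))
    # products stay below 2^53 so double arithmetic is exact
    h <- (h * 48271 + (abs(v) %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under a temporary RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_radboot <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "radboot_error")))
}
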