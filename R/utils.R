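# Internal RNG helpers. All randomness in the package flows through seeds
# derived deterministically from a user-facing integer seed, so that cohorts,
# forests and cross-validation folds are reproducible and independent of the
# caller's RNG state and of evaluation order.

#' Derive a reproducible sub-seed
#'
#' Combines an integer seed with further integer (or short character) keys
#' into a new seed in `[1, 2^31 - 2]`. Used to give each subject, tree,
#' feature, fold and network its own deterministic RNG sub-stream.
#'
#' @param seed Integer base seed.
#' @param ... Integers or short strings identifying the sub-stream
#'   (e.g. tree index, feature index).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "fold", 12)
derive_seed <- function(seed, ...) {
  parts <- list(...)
  keys <- unlist(lapply(parts, function(p) {
    if (is.character(p)) utf8ToInt(p) else as.numeric(p)
  }), use.names = FALSE)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; all arithmetic stays < 2^53
  s <- as.numeric(seed) %% m
  for (k in keys) {
    s <- (s * 69069 + (k %% m) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# Evaluate `code` under `set.seed(seed)` while preserving the caller's RNG
# state (restored on exit, including the no-seed-yet case).
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

# stop() with a consistent prefix-free message assembled via sprintf
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
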