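#' Derive a child seed from a campaign seed
#'
#' All randomness in the package flows from a single user-supplied seed;
#' sub-tasks (per-round sampling, per-well candidate pools, restarts) use
#' seeds derived deterministically from it. The result stays below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param key integer offset identifying the sub-task.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(key))
  as.integer((abs(seed) + 1000003 * abs(key)) %% 2147483647)
}

# Numerically stable softplus; monotone, hence argmax-preserving.
softplus <- function(x) {
  out <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rpe <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_rpe <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
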