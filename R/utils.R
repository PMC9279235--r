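#' Derive reproducible sub-seeds from a master seed
#'
#' All randomness in a multi-stage experiment flows from one master seed.
#' Stage and per-entity seeds are drawn from the RNG stream seeded with the
#' master seed, so any stage can be re-run in isolation given its derived
#' seed. Seeds are kept within the 32-bit integer range.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of `n` sub-seeds in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

`%theninform%` <- function(cond, msg) {
  if (isTRUE(cond)) inform(msg)
  invisible(cond)
}
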