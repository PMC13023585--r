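#' Round half away from zero
#'
#' Deterministic commercial rounding used for edge-count targets, where
#' `base::round()`'s round-half-even rule would be surprising.
#'
#' @param x numeric vector
#' @return integer vector
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Derive reproducible child seeds from one root seed
#'
#' All stochastic stages draw their seeds from one root via this helper so a
#' single integer reproduces a whole run (per-subject, per-surrogate,
#' per-permutation substreams).
#'
#' @param root_seed integer root seed
#' @param n number of child seeds
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`
#' @export
derive_seeds <- function(root_seed, n) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(root_seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
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

#' Run an expression with a local RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_plvnet <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
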