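# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a vector of independent sub-seeds from a master seed
#'
#' Sub-seeds are drawn once, up front, so serial and parallel execution of
#' the consumers agree replicate-for-replicate. All seeds stay below 2^31.
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_localmfa <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "localmfa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
assert_that <- function(ok, msg, class = "localmfa_validation_error") {
  if (!isTRUE(ok)) stop_localmfa(msg, class)
  invisible(TRUE)
}
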