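#' Derive a child seed from a root seed
#'
#' Hierarchical seed derivation: every random stage (and every cell/trial
#' stream within a stage) gets its own deterministic child seed, so that
#' e.g. adding cells to a synthetic session does not reshuffle the random
#' streams of existing cells. Uses a simple multiplicative hash folded into
#' the positive 31-bit integer range accepted by [set.seed()].
#'
#' @param root integer root seed.
#' @param ... integer (or coercible) stream indices, hashed in order.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(root, ...) {
  idx <- c(...)
  h <- as.double(root) %% 2147483647
  for (k in seq_along(idx)) {
    v <- as.double(idx[[k]])
    # 48271 and 69621 are classic Lehmer multipliers; all arithmetic stays
    # below 2^53 so the double math is exact
    h <- (h * 48271 + (v + 1) * 69621 + k) %% 2147483647
  }
  as.integer(h + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so library functions stay free of RNG side effects.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' The four cell classes
#' @keywords internal
CELL_CLASSES <- c("PYR", "PV", "SOM", "VIP")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
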