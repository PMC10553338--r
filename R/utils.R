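# Small shared helpers.

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`, so
#' that seeded package operations do not perturb user randomness.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' Deterministic fan-out so that adding a stage never perturbs the randomness
#' another stage receives. Result is always a valid 32-bit integer seed.
#'
#' @param seed global integer seed.
#' @param name character stage name.
#' @return integer sub-seed in `[0, 2^31 - 1]`.
#' @export
stage_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
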