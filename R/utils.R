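#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit. With `seed = NULL` the expression is
#' evaluated against the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child RNG seed from a root seed and a path of tokens
#'
#' Deterministically folds integer or character tokens into a root seed with
#' a multiplicative congruential mix modulo 2^31 - 1, so that independent
#' parts of a computation (samples, proposals, replicates) each get their own
#' reproducible stream and the result does not depend on evaluation order.
#'
#' @param root integer root seed.
#' @param ... integer or character tokens identifying the child stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483647
  h <- as.numeric(root) %% m
  for (tok in list(...)) {
    if (is.character(tok)) tok <- sum(utf8ToInt(tok))
    for (t in as.numeric(tok)) {
      h <- (h * 69069 + t + 1) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
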